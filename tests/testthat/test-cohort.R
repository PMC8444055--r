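idx <- as.Date("2017-01-01")

test_that("eligibility screen applies each criterion once, with accounting", {
  fx <- worked_fixture()
  elig <- apply_eligibility(fx, idx, "BP")
  expect_equal(attr(elig, "n_input"), 20L)
  expect_equal(nrow(elig), 17L)
  excl <- attr(elig, "exclusions")
  expect_equal(sum(excl$removed[excl$criterion != "retained"]), 3L)
  # counts reconcile: input = retained + removals
  expect_equal(attr(elig, "n_input"),
               nrow(elig) + sum(excl$removed[excl$criterion != "retained"]))
  expect_false("P18" %in% elig$patient_id)  # under 18
  expect_false("P19" %in% elig$patient_id)  # died 200 days post-index
  expect_false("P20" %in% elig$patient_id)  # resident under 2 years
  # every fixture patient has exactly 12 pre-index contacts
  expect_true(all(elig$n_contacts == 12L))
  # ages at index
  expect_equal(elig$age_at_index[elig$patient_id == "P01"], 70)
  expect_equal(elig$age_at_index[elig$patient_id == "P02"], 60)
})

test_that("exposure requires an episode open at the index date", {
  open <- data.frame(diagnosis = "depression",
                     episode_open = as.Date("2015-01-01"),
                     episode_close = as.Date(NA))
  expect_true(ascertain_exposure(open, idx)$exposed)
  closed <- data.frame(diagnosis = "depression",
                       episode_open = as.Date("2015-01-01"),
                       episode_close = as.Date("2016-06-30"))
  expect_false(ascertain_exposure(closed, idx)$exposed)
  # close after index still counts as open at index
  closing_later <- data.frame(diagnosis = "bipolar disorder",
                              episode_open = as.Date("2015-01-01"),
                              episode_close = as.Date("2017-06-30"))
  expect_true(ascertain_exposure(closing_later, idx)$exposed)
  # opened after index does not count
  future <- data.frame(diagnosis = "depression",
                       episode_open = as.Date("2017-03-01"),
                       episode_close = as.Date(NA))
  expect_false(ascertain_exposure(future, idx)$exposed)
  # severity tie-break across concurrent open episodes
  two <- data.frame(diagnosis = c("bipolar disorder", "depression"),
                    episode_open = as.Date(c("2014-01-01", "2015-01-01")),
                    episode_close = as.Date(c(NA, NA)))
  expect_equal(ascertain_exposure(two, idx)$diagnosis_category,
               "bipolar disorder")
  three <- rbind(two, data.frame(diagnosis = "schizophrenia",
                                 episode_open = as.Date("2016-01-01"),
                                 episode_close = as.Date(NA)))
  expect_equal(ascertain_exposure(three, idx)$diagnosis_category,
               "schizophrenia")
  expect_false(ascertain_exposure(NULL, idx)$exposed)
})

test_that("matching enforces gender, age and contact constraints", {
  exposed <- data.frame(patient_id = "E1", gender = "F", age_at_index = 65,
                        n_contacts = 10)
  pool <- data.frame(patient_id = paste0("C", 1:4), gender = "F",
                     age_at_index = c(64, 65, 66, 67), n_contacts = 10)
  sets <- match_comparators(exposed, pool, seed = 5)
  got <- sets$patient_id[sets$exposed == 0]
  expect_setequal(got, c("C1", "C2", "C3"))   # C4 is 2 years older
  # sets of fewer than three comparators are retained
  sets2 <- match_comparators(exposed, pool[1:2, ], seed = 5)
  expect_equal(sum(sets2$exposed == 0), 2L)
  expect_equal(nrow(sets2), 3L)
  # gender must agree
  poolM <- transform(pool, gender = "M")
  sets3 <- match_comparators(exposed, poolM, seed = 5)
  expect_equal(nrow(sets3), 0L)
  expect_equal(attr(sets3, "unmatched"), "E1")
  expect_error(match_comparators(exposed, pool, ratio = 0), "ratio")
})

test_that("matching is seeded-deterministic and never reuses a comparator", {
  set.seed(91)
  n_e <- 40; n_p <- 400
  exposed <- data.frame(patient_id = paste0("E", 1:n_e),
                        gender = sample(c("M", "F"), n_e, TRUE),
                        age_at_index = sample(40:80, n_e, TRUE),
                        n_contacts = rpois(n_e, 20))
  pool <- data.frame(patient_id = paste0("C", 1:n_p),
                     gender = sample(c("M", "F"), n_p, TRUE),
                     age_at_index = sample(40:80, n_p, TRUE),
                     n_contacts = rpois(n_p, 20))
  s1 <- match_comparators(exposed, pool, seed = 17)
  s2 <- match_comparators(exposed, pool, seed = 17)
  expect_identical(s1, s2)
  comp <- s1$patient_id[s1$exposed == 0]
  expect_equal(anyDuplicated(comp), 0L)
  # post-hoc constraint audit on every set
  br <- unique(quantile(pool$n_contacts, seq(0.1, 0.9, 0.1), names = FALSE))
  pbin <- findInterval(pool$n_contacts, br)
  ebin <- findInterval(exposed$n_contacts, br)
  for (s in unique(s1$set_id)) {
    m <- s1[s1$set_id == s, ]
    e <- exposed[exposed$patient_id == m$patient_id[m$exposed == 1], ]
    cmp <- pool[pool$patient_id %in% m$patient_id[m$exposed == 0], ]
    expect_true(all(cmp$gender == e$gender))
    expect_true(all(abs(cmp$age_at_index - e$age_at_index) <= 1))
    expect_true(all(pbin[match(cmp$patient_id, pool$patient_id)] ==
                      ebin[match(e$patient_id, exposed$patient_id)]))
    expect_lte(nrow(cmp), 3L)
    expect_gte(nrow(cmp), 1L)
  }
})

test_that("standardised difference formulas", {
  expect_equal(standardized_difference(c(0, 1, 0, 1), c(1, 0, 1, 0)), 0)
  # p1 = 0.3, p2 = 0.2: 0.1 / sqrt(0.185)
  x <- c(rep(1, 3), rep(0, 7)); y <- c(rep(1, 2), rep(0, 8))
  expect_equal(standardized_difference(x, y, "binary"), 0.1 / sqrt(0.185),
               tolerance = 1e-12)
  expect_equal(round(standardized_difference(x, y, "binary"), 4), 0.2325)
  # continuous: |m1 - m2| / sqrt((s1^2 + s2^2)/2)
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  expect_equal(standardized_difference(a, b, "continuous"),
               1 / sqrt((var(a) + var(b)) / 2))
  # zero pooled variance with unequal means flags infinite
  expect_equal(standardized_difference(rep(1, 5), rep(0, 5)), Inf)
  expect_equal(standardized_difference(rep(1, 5), rep(1, 5)), 0)
  expect_error(standardized_difference(numeric(0), 1), "non-empty")
  bt <- balance_table(data.frame(exposed = rep(c(1, 0), each = 10),
                                 v = c(rep(1, 6), rep(0, 4),
                                       rep(1, 2), rep(0, 8))), "v")
  expect_true(bt$flagged)
})

test_that("covariates honour the lookback window and bin boundaries", {
  pats <- data.frame(patient_id = c("A", "B", "C", "D"),
                     mcs_score = c(1, 2, 3, 6))
  tabs <- list(
    patients = pats,
    dispensations = data.frame(
      patient_id = c("A", "B"), drug_class = "NSAID",
      date = c(idx - 100, idx - 1100), amount_ddd = 30),
    hospital_stays = data.frame(
      patient_id = "C", diagnosis = "CARDIOVASCULAR",
      admission_date = idx - 200, discharge_date = idx - 190))
  cov <- derive_covariates(tabs, c("A", "B", "C", "D"), idx)
  expect_true(cov$nsaid[cov$patient_id == "A"])
  expect_false(cov$nsaid[cov$patient_id == "B"])  # 3 years before index
  expect_true(cov$cardiovascular_disease[cov$patient_id == "C"])
  expect_false(cov$cardiovascular_disease[cov$patient_id == "A"])
  # cutpoints c(1,3,5): a boundary score belongs to the lower category
  expect_equal(cov$mcs_category, c(1L, 2L, 2L, 4L))
  expect_error(derive_covariates(tabs, "A", idx, codelists = NULL),
               "codelists")
})

test_that("contact counting matches its definition", {
  tabs <- list(
    dispensations = data.frame(patient_id = c("A", "A", "A"),
                               date = idx - c(10, 800, 100),
                               drug_class = "BP", amount_ddd = 30),
    hospital_stays = data.frame(patient_id = "A", admission_date = idx - 50,
                                discharge_date = idx - 45),
    outpatient_services = data.frame(patient_id = c("A", "B"),
                                     date = c(idx - 5, idx - 9),
                                     service_code = "VISIT"))
  ct <- count_contacts(tabs, idx)
  expect_equal(unname(ct["A"]), 4L)  # 2 in-window dispensations + 1 stay + 1 visit
  expect_equal(unname(ct["B"]), 1L)
})
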