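test_that("scenario validation rejects malformed parameters", {
  expect_error(claims_scenario(smi_prevalence = 1.2), "probabilities")
  expect_error(claims_scenario(n_patients = 0), "n_patients")
  expect_error(claims_scenario(hospital_rate = -1), "rates")
  expect_s3_class(claims_scenario(), "claims_scenario")
})

test_that("identical config and seed reproduce the tables exactly", {
  sc <- claims_scenario(n_patients = 300, smi_prevalence = 0.1, seed = 7)
  b1 <- simulate_claims(sc)
  b2 <- simulate_claims(sc)
  for (tb in c("patients", "dispensations", "hospital_stays",
               "outpatient_services", "mental_health_records"))
    expect_identical(b1[[tb]], b2[[tb]])
  b3 <- simulate_claims(claims_scenario(n_patients = 300,
                                        smi_prevalence = 0.1, seed = 8))
  expect_false(identical(b1$dispensations, b3$dispensations))
})

test_that("empirical exposure prevalence tracks the target", {
  for (prev in c(0.02, 0.15)) {
    sc <- claims_scenario(n_patients = 4000, smi_prevalence = prev,
                          seed = 123)
    b <- simulate_claims(sc)
    open <- is.na(b$mental_health_records$episode_close)
    p_hat <- sum(open) / nrow(b$patients)
    expect_lt(abs(p_hat - prev), 3 * sqrt(prev * (1 - prev) / 4000))
  }
})

test_that("generator truth is realised through the era machinery", {
  sc <- claims_scenario(n_patients = 500, smi_prevalence = 0.1, seed = 99,
                        drug_class_mix = c(BP = 1, LIPID = 0, GLUCOSE = 0.4))
  b <- simulate_claims(sc)
  w <- followup_window(sc$index_date)
  tr <- b$truth[b$truth$drug_class == "BP", ]
  adh <- pdc_table(b$dispensations, tr$patient_id, "BP", w,
                   hospital_stays = b$hospital_stays)
  # realised high/not-high equals the latent draw for every patient
  expect_equal(adh$high_at_75, tr$high_adherence)
  # and covered days hit the planted target whenever stays do not exceed it
  expect_true(mean(adh$covered_days == tr$target_covered_days) > 0.98)
  # clinical controls: realised >=4-of-5 equals the latent draw
  prof <- pdcmatch:::controls_table(b$outpatient_services,
                                    b$truth_controls$patient_id, w,
                                    default_control_codes())
  expect_equal(prof$high_controls_at_4, b$truth_controls$high_controls)
})

test_that("null scenario without confounding gives a crude OR near 1", {
  sc <- claims_scenario(n_patients = 6000, smi_prevalence = 0.25,
                        true_log_or = 0,
                        confounder_effects = list(
                          smi_gender_f = 0, smi_age_per_year = 0,
                          smi_contact_decile = 0, adh_gender_f = 0,
                          adh_age_per_year = 0, adh_contact_decile = 0),
                        drug_class_mix = c(BP = 1, LIPID = 0, GLUCOSE = 0),
                        seed = 5)
  b <- simulate_claims(sc)
  tr <- b$truth
  tab <- table(tr$exposed, tr$high_adherence)
  crude_or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log(crude_or)), 3 * se)
})

test_that("planted conditional effect is recovered without bias", {
  # 200 small replicates through the set-level simulator + exact fit
  set.seed(77)
  true_beta <- log(0.76)
  est <- se2 <- numeric(200)
  for (r in 1:200) {
    sm <- simulate_matched_sets(150, true_log_or = true_beta)
    f <- clr(y ~ exposed, sm, "set_id", quiet = TRUE)
    est[r] <- coef(f)[[1]]; se2[r] <- vcov(f)[1, 1]
  }
  mc_se <- sd(est) / sqrt(200)
  expect_lt(abs(mean(est) - true_beta), 2 * mc_se + 0.01)
  # Wald SEs agree with the Monte-Carlo spread
  expect_equal(mean(sqrt(se2)), sd(est), tolerance = 0.15)
})

test_that("bundle export writes the documented CSV schema", {
  sc <- claims_scenario(n_patients = 50, seed = 2)
  b <- simulate_claims(sc)
  dir <- tempfile("bundle")
  paths <- write_bundle(b, dir)
  expect_true(all(file.exists(paths)))
  pat <- read.csv(file.path(dir, "patients.csv"))
  expect_true(all(c("patient_id", "gender", "birth_date", "residency_start",
                    "death_date", "emigration_date", "mcs_score")
                  %in% names(pat)))
  disp <- read.csv(file.path(dir, "dispensations.csv"))
  expect_true(all(c("patient_id", "date", "drug_class", "amount_ddd")
                  %in% names(disp)))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$seed, 2L)
  expect_equal(man$config_hash, b$manifest$config_hash)
})

test_that("worked fixture reproduces its hand-computed values", {
  fx <- worked_fixture()
  expect_equal(nrow(fx$patients), 20L)
  # P01: 61-day gap makes exactly two eras, the second with 3 dispensations
  d01 <- fx$dispensations[fx$dispensations$patient_id == "P01", ]
  e01 <- build_eras(d01)
  expect_equal(nrow(e01), 2L)
  expect_equal(e01$n_dispensations, c(1L, 3L))
  expect_true(is_prevalent_user(e01, d01, as.Date("2017-01-01")))
  # P02: full-year coverage, PDC exactly 1
  w <- followup_window("2017-01-01")
  d02 <- fx$dispensations[fx$dispensations$patient_id == "P02", ]
  expect_equal(compute_pdc(d02, w)$pdc, 1.0)
  # P06: 100 dispensed + 30 bridged hospital days
  d06 <- fx$dispensations[fx$dispensations$patient_id == "P06", ]
  s06 <- fx$hospital_stays[fx$hospital_stays$patient_id == "P06", ]
  r06 <- compute_pdc(d06, w, s06)
  expect_equal(r06$covered_days, 130L)
  expect_equal(as.character(r06$category), "low")
  # diabetic P03: 2 HbA1c + 1 lipid + 1 creatinine -> 3 of 5, not high at 4
  p03 <- assess_clinical_controls(
    fx$outpatient_services[fx$outpatient_services$patient_id == "P03" &
                             fx$outpatient_services$service_code != "VISIT", ],
    w)
  expect_equal(p03$n_satisfied, 3L)
  expect_false(p03$high_controls_at_4)
  expect_true(p03$high_controls_at_3)
})
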