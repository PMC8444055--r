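#' Scenario configuration for the synthetic claims generator
#'
#' Bundles and validates the parameters that define a simulated
#' healthcare-utilisation scenario.  The planted `true_log_or` is the
#' conditional (within matched set) log odds ratio of high drug adherence
#' for exposed versus unexposed patients — the quantity the downstream
#' matched analysis is expected to recover.  Matching variables (gender,
#' age, healthcare-contact volume) influence both exposure probability and
#' adherence through `confounder_effects`, so crude and conditional effects
#' differ by design.
#'
#' @param n_patients number of patients to simulate.
#' @param index_date cohort entry date (default `"2017-01-01"`).
#' @param smi_prevalence target probability of severe mental illness
#'   (exposure); the exposure-model intercept is calibrated so the
#'   population mean matches it.
#' @param true_log_or planted conditional log odds ratio of high drug
#'   adherence (PDC >= 75%) for exposed vs unexposed (default
#'   `log(0.76)`).
#' @param controls_true_log_or planted conditional log odds ratio of high
#'   clinical-control adherence (>= 4 of 5) among diabetics (default
#'   `log(0.82)`).
#' @param baseline_high_adherence_prob probability of high drug adherence
#'   for an unexposed patient at reference covariate values.
#' @param baseline_high_controls_prob same for the clinical-control bundle.
#' @param confounder_effects named list of log-odds contributions of the
#'   matching variables: `smi_gender_f`, `smi_age_per_year`,
#'   `smi_contact_decile` enter the exposure model;  `adh_gender_f`,
#'   `adh_age_per_year`, `adh_contact_decile` enter both adherence models.
#' @param drug_class_mix named per-class membership probabilities over
#'   `BP`, `LIPID`, `GLUCOSE`; classes are not exclusive (a patient on two
#'   therapies belongs to both groups), and patients drawing no class are
#'   assigned one proportionally.
#' @param control_rates named yearly intensities of the five diabetes
#'   controls, used to draw service counts beyond the satisfying minimum.
#' @param hospital_rate admissions per person-year.
#' @param death_emigration_prob probability of death or emigration within
#'   the follow-up year.
#' @param visit_rate out-patient visits per person-year in the lookback
#'   (drives contact volume).
#' @param nonprevalent_prob fraction of patients given too few pre-index
#'   dispensations to qualify as prevalent users.
#' @param underage_prob,short_residency_prob small fractions violating the
#'   age and residency criteria, to exercise the eligibility screen.
#' @param seed integer seed; identical config + seed reproduces the tables
#'   byte for byte.
#' @return object of class `claims_scenario` (a validated list).
#' @export
claims_scenario <- function(n_patients = 1000,
                            index_date = "2017-01-01",
                            smi_prevalence = 0.02,
                            true_log_or = log(0.76),
                            controls_true_log_or = log(0.82),
                            baseline_high_adherence_prob = 0.50,
                            baseline_high_controls_prob = 0.50,
                            confounder_effects = list(
                              smi_gender_f = 0.30, smi_age_per_year = -0.015,
                              smi_contact_decile = 0.12,
                              adh_gender_f = 0.20, adh_age_per_year = 0.010,
                              adh_contact_decile = 0.15),
                            drug_class_mix = c(BP = 0.75, LIPID = 0.35,
                                               GLUCOSE = 0.20),
                            control_rates = c(hba1c = 2.2, lipid_profile = 1.4,
                                              serum_creatinine = 1.3,
                                              urine_albumin = 1.0,
                                              eye_exam = 0.9),
                            hospital_rate = 0.10,
                            death_emigration_prob = 0.02,
                            visit_rate = 3,
                            nonprevalent_prob = 0.05,
                            underage_prob = 0.01,
                            short_residency_prob = 0.01,
                            seed = 1L) {
  probs <- c(smi_prevalence = smi_prevalence,
             baseline_high_adherence_prob = baseline_high_adherence_prob,
             baseline_high_controls_prob = baseline_high_controls_prob,
             death_emigration_prob = death_emigration_prob,
             nonprevalent_prob = nonprevalent_prob,
             underage_prob = underage_prob,
             short_residency_prob = short_residency_prob,
             drug_class_mix)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stop_config("probabilities must lie in [0, 1]: ",
                paste(names(probs)[!is.finite(probs) | probs < 0 | probs > 1],
                      collapse = ", "))
  if (!is.numeric(n_patients) || n_patients < 1)
    stop_config("n_patients must be >= 1")
  if (any(c(hospital_rate, visit_rate, unlist(control_rates)) < 0))
    stop_config("rates must be non-negative")
  cfg <- list(n_patients = as.integer(n_patients), index_date = index_date,
              smi_prevalence = smi_prevalence, true_log_or = true_log_or,
              controls_true_log_or = controls_true_log_or,
              baseline_high_adherence_prob = baseline_high_adherence_prob,
              baseline_high_controls_prob = baseline_high_controls_prob,
              confounder_effects = confounder_effects,
              drug_class_mix = drug_class_mix,
              control_rates = control_rates,
              hospital_rate = hospital_rate,
              death_emigration_prob = death_emigration_prob,
              visit_rate = visit_rate,
              nonprevalent_prob = nonprevalent_prob,
              underage_prob = underage_prob,
              short_residency_prob = short_residency_prob,
              seed = as.integer(seed))
  class(cfg) <- "claims_scenario"
  cfg
}

#' @export
print.claims_scenario <- function(x, ...) {
  cat("Synthetic claims scenario:", x$n_patients, "patients, index",
      as.character(x$index_date), "\n")
  cat(sprintf("  exposure prevalence %.3f, planted OR %.3f (drugs), %.3f (controls)\n",
              x$smi_prevalence, exp(x$true_log_or),
              exp(x$controls_true_log_or)))
  cat("  seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic healthcare-utilisation registry
#'
#' Emits the five registry-style tables (patients, drug dispensations,
#' hospital stays, out-patient services, mental-health records) with a
#' known ground-truth structure.  Each patient-class carries a latent
#' high-adherence indicator drawn from a logistic model with the planted
#' conditional log odds ratio for exposure and the configured
#' matching-variable effects; the dispensation stream is then laid down in
#' 30-DDD packs so that the days covered in the follow-up window — after
#' hospital-stay bridging — realise the drawn adherence category through
#' the same drug-era machinery the pipeline applies.  Diabetic patients
#' receive control-service bundles realised from a latent high-controls
#' indicator in the same way.
#'
#' @param config a [claims_scenario()].
#' @return object of class `claims_bundle`: list of tables `patients`,
#'   `dispensations`, `hospital_stays`, `outpatient_services`,
#'   `mental_health_records`, plus `truth` (per patient-class latent
#'   indicators and targets, for tests), `config`, and a `manifest`
#'   recording seed and a hash of the configuration.
#' @export
simulate_claims <- function(config) {
  stopifnot(inherits(config, "claims_scenario"))
  set.seed(config$seed)
  n <- config$n_patients
  idx <- as_day(config$index_date)
  ce <- config$confounder_effects
  id <- sprintf("P%06d", seq_len(n))
  gender <- ifelse(runif(n) < 0.55, "F", "M")
  age <- pmin(95L, pmax(18L, as.integer(round(rnorm(n, 65, 12)))))
  under <- runif(n) < config$underage_prob
  age[under] <- sample(12:17, sum(under), replace = TRUE)
  birth_day <- idx - round(age * 365.25) - sample(30:300, n, replace = TRUE)
  residency <- idx - 731 - sample(0:3000, n, replace = TRUE)
  shortres <- runif(n) < config$short_residency_prob
  residency[shortres] <- idx - sample(30:600, sum(shortres), replace = TRUE)
  death_day <- rep(NA_real_, n); emig_day <- rep(NA_real_, n)
  gone <- runif(n) < config$death_emigration_prob
  gone_day <- idx + sample(0:364, n, replace = TRUE)
  is_death <- runif(n) < 0.5
  death_day[gone & is_death] <- gone_day[gone & is_death]
  emig_day[gone & !is_death] <- gone_day[gone & !is_death]

  # drug-class membership (non-exclusive)
  classes <- names(config$drug_class_mix)
  member <- sapply(classes, function(cl)
    runif(n) < config$drug_class_mix[[cl]])
  member <- matrix(member, nrow = n, dimnames = list(NULL, classes))
  none <- rowSums(member) == 0
  if (any(none)) {
    pickcl <- sample(classes, sum(none), replace = TRUE,
                     prob = config$drug_class_mix / sum(config$drug_class_mix))
    member[cbind(which(none), match(pickcl, classes))] <- TRUE
  }

  # pre-index dispensations: a chain of 30-DDD packs ending at the index
  # date (prevalent users); a small fraction get only a 2-pack chain
  pc_pat <- rep(seq_len(n), ncol(member))[as.vector(member)]
  pc_cls <- rep(classes, each = n)[as.vector(member)]
  npc <- length(pc_pat)
  n_pre <- sample(4:8, npc, replace = TRUE)
  n_pre[runif(npc) < config$nonprevalent_prob] <- 2L
  pre_pat <- rep(pc_pat, n_pre)
  pre_cls <- rep(pc_cls, n_pre)
  pre_off <- sequence(n_pre)                     # 1..n_pre within stream
  pre_day <- idx - 30 * (rep(n_pre, n_pre) - pre_off + 1)
  disp <- data.frame(patient_id = id[pre_pat], date = pre_day,
                     drug_class = pre_cls, amount_ddd = 30,
                     stringsAsFactors = FALSE)

  # cotreatment dispensations in the lookback (baseline covariates)
  cot <- lapply(c(NSAID = 0.25, ANTITHROMBOTIC = 0.15, RESP = 0.10),
                function(p) which(runif(n) < p))
  for (code in names(cot)) {
    who <- cot[[code]]
    if (!length(who)) next
    k <- sample(1:3, length(who), replace = TRUE)
    disp <- rbind(disp, data.frame(
      patient_id = rep(id[who], k),
      date = idx - sample(1:730, sum(k), replace = TRUE),
      drug_class = code, amount_ddd = 30, stringsAsFactors = FALSE))
  }

  # hospital stays: lookback (comorbidity + contacts) and follow-up
  # (immeasurable time); short stays, non-overlapping by construction
  mk_stays <- function(n_stays, start_lo, start_hi) {
    pat <- rep(seq_len(n), n_stays)
    adm <- start_lo + floor(runif(length(pat)) * (start_hi - start_lo))
    len <- 3 + rpois(length(pat), 5)
    data.frame(patient_id = id[pat],
               admission_date = adm, discharge_date = adm + len,
               diagnosis = sample(c("CARDIOVASCULAR", "RENAL", "OTHER"),
                                  length(pat), replace = TRUE,
                                  prob = c(0.4, 0.2, 0.4)),
               stringsAsFactors = FALSE)
  }
  n_pre_stay <- rpois(n, 2 * config$hospital_rate)
  pre_stays <- mk_stays(n_pre_stay, idx - 730, idx - 10)
  n_post_stay <- rpois(n, config$hospital_rate)
  post_stays <- mk_stays(n_post_stay, idx, idx + 350)
  stays <- rbind(pre_stays, post_stays)

  # out-patient visits in the lookback (contact volume)
  n_visit <- rpois(n, 2 * config$visit_rate)
  visits <- data.frame(patient_id = rep(id, n_visit),
                       date = idx - sample(1:730, sum(n_visit), replace = TRUE),
                       service_code = "VISIT", stringsAsFactors = FALSE)

  # contact volume and its decile, the confounder the matcher balances
  pre_disp_count <- tabulate(pre_pat, nbins = n)
  cot_count <- tabulate(
    match(disp$patient_id[disp$drug_class %in% names(cot)], id), nbins = n)
  contacts <- pre_disp_count + cot_count +
    tabulate(match(pre_stays$patient_id, id), nbins = n) + n_visit
  decile <- contact_decile(contacts)

  # exposure: intercept calibrated so mean probability hits the target
  eta_smi <- ce$smi_gender_f * (gender == "F") +
    ce$smi_age_per_year * (age - 65) +
    ce$smi_contact_decile * (decile - 5.5)
  a0 <- calibrate_intercept(eta_smi, config$smi_prevalence)
  exposed <- runif(n) < plogis(a0 + eta_smi)
  dxs <- sample(c("depression", "bipolar disorder", "schizophrenia",
                  "personality disorder"), n, replace = TRUE,
                prob = c(0.5, 0.2, 0.15, 0.15))
  mh <- data.frame(patient_id = id[exposed],
                   diagnosis = dxs[exposed],
                   episode_open = idx - sample(365:3650, sum(exposed),
                                               replace = TRUE),
                   episode_close = rep(NA_real_, sum(exposed)),
                   stringsAsFactors = FALSE)
  # a few closed (inactive) episodes among the unexposed; such patients are
  # neither exposed nor eligible comparators
  closed <- which(!exposed)[runif(sum(!exposed)) < 0.005]
  if (length(closed)) {
    op <- idx - sample(2000:4000, length(closed), replace = TRUE)
    mh <- rbind(mh, data.frame(patient_id = id[closed],
                               diagnosis = dxs[closed],
                               episode_open = op,
                               episode_close = op + sample(100:900,
                                                           length(closed),
                                                           replace = TRUE),
                               stringsAsFactors = FALSE))
  }

  # latent adherence per patient-class and its realisation as an
  # in-window dispensation stream (30-DDD packs + remainder)
  eta_adh <- qlogis(config$baseline_high_adherence_prob) +
    config$true_log_or * exposed[pc_pat] +
    ce$adh_gender_f * ((gender[pc_pat] == "F") - 0.55) +
    ce$adh_age_per_year * (age[pc_pat] - 65) +
    ce$adh_contact_decile * (decile[pc_pat] - 5.5)
  high <- runif(npc) < plogis(eta_adh)
  target_frac <- draw_pdc_fraction(high)
  target_days <- pmin(365L, pmax(0L, as.integer(round(target_frac * 365))))
  target_days[high] <- pmax(target_days[high], 274L)      # >= 75% of 365
  target_days[!high] <- pmin(target_days[!high], 273L)
  # subtract bridged hospital days so the realised covered count (drug
  # coverage plus bridged stays) equals the target
  supply <- target_days
  has_stay <- id[pc_pat] %in% post_stays$patient_id
  if (any(has_stay)) {
    stay_by_pat <- split(seq_len(nrow(post_stays)), post_stays$patient_id)
    for (k in which(has_stay)) {
      six <- stay_by_pat[[id[pc_pat[k]]]]
      H <- clip_intervals(merge_intervals(post_stays$admission_date[six],
                                          post_stays$discharge_date[six]),
                          idx, idx + 365)
      A <- target_days[k]
      for (rep_i in 1:6) {
        inA <- sum(pmax(0, pmin(H$end, idx + A) - H$start) *
                     (H$start < idx + A))
        A_new <- max(0L, target_days[k] - covered_day_count(H) + as.integer(inA))
        if (A_new == A) break
        A <- A_new
      }
      supply[k] <- A
    }
  }
  k_full <- supply %/% 30L
  remn <- supply - 30L * k_full
  w_pat <- rep(pc_pat, k_full); w_cls <- rep(pc_cls, k_full)
  w_day <- idx + 30 * (sequence(k_full) - 1)
  if (length(w_pat))
    disp <- rbind(disp, data.frame(patient_id = id[w_pat], date = w_day,
                                   drug_class = w_cls, amount_ddd = 30,
                                   stringsAsFactors = FALSE))
  rsel <- remn > 0
  if (any(rsel))
    disp <- rbind(disp, data.frame(patient_id = id[pc_pat[rsel]],
                                   date = idx + 30 * k_full[rsel],
                                   drug_class = pc_cls[rsel],
                                   amount_ddd = remn[rsel],
                                   stringsAsFactors = FALSE))

  # clinical-control services for diabetics, realised from the latent
  # high-controls indicator
  services <- visits
  diab <- which(member[, "GLUCOSE"])
  truth_controls <- NULL
  if (length(diab)) {
    eta_ctl <- qlogis(config$baseline_high_controls_prob) +
      config$controls_true_log_or * exposed[diab] +
      ce$adh_gender_f * ((gender[diab] == "F") - 0.55) +
      ce$adh_age_per_year * (age[diab] - 65) +
      ce$adh_contact_decile * (decile[diab] - 5.5)
    high_ctl <- runif(length(diab)) < plogis(eta_ctl)
    ctl <- realise_controls(id[diab], high_ctl, config$control_rates, idx)
    services <- rbind(services, ctl)
    truth_controls <- data.frame(patient_id = id[diab],
                                 high_controls = high_ctl,
                                 stringsAsFactors = FALSE)
  }

  mcs <- pmin(10L, rpois(n, 0.8 + 0.02 * pmax(0, age - 40) + 0.15 * decile))
  patients <- data.frame(patient_id = id, gender = gender,
                         birth_date = as_date(birth_day),
                         residency_start = as_date(residency),
                         death_date = as_date(death_day),
                         emigration_date = as_date(emig_day),
                         mcs_score = mcs, stringsAsFactors = FALSE)
  disp$date <- as_date(disp$date)
  stays$admission_date <- as_date(stays$admission_date)
  stays$discharge_date <- as_date(stays$discharge_date)
  services$date <- as_date(services$date)
  mh$episode_open <- as_date(mh$episode_open)
  mh$episode_close <- as_date(mh$episode_close)
  o <- order(disp$patient_id, disp$drug_class, disp$date)
  disp <- disp[o, , drop = FALSE]; rownames(disp) <- NULL
  truth <- data.frame(patient_id = id[pc_pat], drug_class = pc_cls,
                      exposed = exposed[pc_pat], high_adherence = high,
                      target_covered_days = target_days,
                      contact_decile = decile[pc_pat],
                      stringsAsFactors = FALSE)
  bundle <- list(patients = patients, dispensations = disp,
                 hospital_stays = stays, outpatient_services = services,
                 mental_health_records = mh,
                 truth = truth, truth_controls = truth_controls,
                 config = config,
                 manifest = list(seed = config$seed,
                                 config_hash = hash_config(config),
                                 n_patients = n))
  class(bundle) <- "claims_bundle"
  bundle
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Synthetic claims bundle:", nrow(x$patients), "patients;",
      nrow(x$dispensations), "dispensations;",
      nrow(x$hospital_stays), "hospital stays;",
      nrow(x$outpatient_services), "out-patient services;",
      nrow(x$mental_health_records), "mental-health records\n")
  invisible(x)
}

# Decile (1..10) of contact counts, ties resolved by average rank so the
# bins are as even as the ties allow.
contact_decile <- function(contacts) {
  r <- rank(contacts, ties.method = "average")
  pmin(10L, 1L + as.integer(floor(10 * (r - 0.5) / length(r))))
}

# Solve the exposure-model intercept so that mean(plogis(a0 + eta)) hits
# the target prevalence for the realised covariate draws.
calibrate_intercept <- function(eta, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  uniroot(function(a) mean(plogis(a + eta)) - target,
          lower = qlogis(target) - 8, upper = qlogis(target) + 8,
          tol = 1e-10)$root
}

# Category-conditional PDC fraction: high draws concentrate in [0.75, 1],
# the remainder spread over the three lower categories.
draw_pdc_fraction <- function(high) {
  n <- length(high)
  frac <- numeric(n)
  nh <- sum(high)
  frac[high] <- 0.75 + 0.25 * rbeta(nh, 4, 1.5)
  n0 <- n - nh
  if (n0) {
    cat3 <- sample(1:3, n0, replace = TRUE, prob = c(0.35, 0.30, 0.35))
    u <- rbeta(n0, 1.3, 1.3)
    lo <- c(0, 0.2501, 0.5001)[cat3]
    hi <- c(0.25, 0.50, 0.7480)[cat3]
    frac[!high] <- lo + u * (hi - lo)
  }
  frac
}

# Emit control-service rows realising the latent high/not-high category:
# high means 4 or 5 of the controls satisfied, not-high at most 3.
realise_controls <- function(ids, high_ctl, rates, idx) {
  controls <- c("hba1c", "lipid_profile", "serum_creatinine",
                "urine_albumin", "eye_exam")
  code1 <- c(hba1c = "HBA1C", lipid_profile = "CHOL_TOT",
             serum_creatinine = "CREATININE", urine_albumin = "URINE_ALBUMIN",
             eye_exam = "EYE_EXAM")
  need <- c(2L, 1L, 1L, 1L, 1L)
  m <- length(ids)
  n_sat <- integer(m)
  n_sat[high_ctl] <- sample(4:5, sum(high_ctl), replace = TRUE,
                            prob = c(0.5, 0.5))
  n_sat[!high_ctl] <- sample(0:3, sum(!high_ctl), replace = TRUE,
                             prob = c(0.15, 0.20, 0.30, 0.35))
  # choose which n_sat of the five controls are satisfied: rank a uniform
  # draw per (patient, control) and keep the n_sat smallest
  U <- matrix(runif(5 * m), m, 5)
  rnk <- matrix(1L, m, 5)
  for (j in 1:5) for (l in 1:5) if (l != j)
    rnk[, j] <- rnk[, j] + (U[, l] < U[, j])
  sat <- rnk <= n_sat
  cnt <- matrix(0L, m, 5)
  for (j in 1:5) {
    extra <- rpois(m, max(0, rates[[controls[j]]] - need[j]))
    cnt[, j] <- ifelse(sat[, j], need[j] + extra, 0L)
  }
  # an unsatisfied hba1c may still have a single assay
  cnt[, 1] <- cnt[, 1] + ifelse(!sat[, 1], rbinom(m, 1L, 0.4), 0L)
  tot <- sum(cnt)
  if (tot == 0L)
    return(data.frame(patient_id = character(0), date = numeric(0),
                      service_code = character(0), stringsAsFactors = FALSE))
  pat <- character(0); code <- character(0)
  for (j in 1:5) {
    pat <- c(pat, rep(ids, cnt[, j]))
    code <- c(code, rep.int(code1[[controls[j]]], sum(cnt[, j])))
  }
  data.frame(patient_id = pat,
             date = idx + sample(0:364, tot, replace = TRUE),
             service_code = code, stringsAsFactors = FALSE)
}

hash_config <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Directly simulate matched-set outcome data
#'
#' Set-level shortcut past the claims machinery: each set has one exposed
#' member and `ratio` comparators sharing a set-specific intercept (the
#' conditional analogue of exact matching), and outcomes are Bernoulli with
#' `logit p = intercept + true_log_or x exposed`.  Used for calibration and
#' parameter-recovery studies where thousands of replicates are needed.
#'
#' @param n_sets number of matched sets.
#' @param ratio comparators per exposed (default 3).
#' @param true_log_or conditional log odds ratio (default 0).
#' @param baseline_p outcome probability at the median set (default 0.5).
#' @param set_sd standard deviation of set intercepts on the logit scale
#'   (heterogeneity induced by the matching variables; default 0.6).
#' @param seed optional integer seed.
#' @return data frame with `set_id`, `exposed` (1/0), `y`.
#' @export
simulate_matched_sets <- function(n_sets, ratio = 3, true_log_or = 0,
                                  baseline_p = 0.5, set_sd = 0.6,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u <- rnorm(n_sets, qlogis(baseline_p), set_sd)
  m <- ratio + 1L
  set_id <- rep(seq_len(n_sets), each = m)
  exposed <- rep(c(1L, rep.int(0L, ratio)), n_sets)
  p <- plogis(u[set_id] + true_log_or * exposed)
  data.frame(set_id = set_id, exposed = exposed,
             y = as.integer(runif(n_sets * m) < p))
}

#' Export a claims bundle as CSV tables with a scenario manifest
#'
#' Writes the five registry tables as CSV (ISO-8601 dates), the scenario
#' configuration as YAML, and a manifest recording the seed and config
#' hash.
#'
#' @param bundle a [simulate_claims()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("patients", "dispensations", "hospital_stays",
              "outpatient_services", "mental_health_records")
  paths <- character(0)
  for (tb in tables) {
    p <- file.path(dir, paste0(tb, ".csv"))
    write.csv(bundle[[tb]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  cfg <- bundle$config
  cfg$drug_class_mix <- as.list(cfg$drug_class_mix)
  cfg$control_rates <- as.list(cfg$control_rates)
  yaml::write_yaml(unclass(cfg), file.path(dir, "scenario.yaml"))
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yaml"))
  invisible(c(paths, file.path(dir, c("scenario.yaml", "manifest.yaml"))))
}
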