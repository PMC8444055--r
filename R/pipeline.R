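#' Batch PDC computation for many patients at once
#'
#' Vectorised equivalent of calling [compute_pdc()] per patient for one
#' drug class: drug-coverage intervals come from a single era scan, and
#' hospital-stay bridging is resolved per patient only where post-index
#' stays exist.  Results are identical to the per-patient function (this is
#' asserted by the test suite).
#'
#' @param dispensations dispensation table (may contain many patients and
#'   classes; filtered to `drug_class`).
#' @param patient_ids patients to score (zero coverage when absent from the
#'   table).
#' @param drug_class class to score.
#' @param window a [followup_window()].
#' @param hospital_stays optional stays table for bridging.
#' @param gap_days,bridge,spillover,thresholds as in [compute_pdc()].
#' @return data frame: `patient_id`, `covered_days`, `pdc`, `category`,
#'   and one `high_at_*` column per threshold.
#' @export
pdc_table <- function(dispensations, patient_ids, drug_class, window,
                      hospital_stays = NULL, gap_days = 60,
                      bridge = c("any_prior_era", "active", "none"),
                      spillover = TRUE, thresholds = c(0.70, 0.75, 0.80)) {
  bridge <- match.arg(bridge)
  ids <- as.character(patient_ids)
  w0 <- as_day(window$start); w1 <- as_day(window$end)
  wd <- as.integer(w1 - w0)
  disp <- dispensations[dispensations$drug_class == drug_class &
                          as.character(dispensations$patient_id) %in% ids, ,
                        drop = FALSE]
  drug_days <- setNames(integer(length(ids)), ids)
  runs <- NULL
  era_info <- NULL
  if (nrow(disp)) {
    scan <- era_scan_table(disp, gap_days = gap_days)
    era_first <- !duplicated(scan$era)
    era_info <- data.frame(patient_id = as.character(scan$patient_id)[era_first],
                           start = scan$day[era_first],
                           end = as.numeric(tapply(scan$cov_end, scan$era,
                                                   max)),
                           stringsAsFactors = FALSE)
    if (!spillover) {
      # numerator from in-window dispensations only (rechained from scratch)
      scan <- scan[scan$day >= w0, , drop = FALSE]
      if (nrow(scan))
        scan <- era_scan_table(scan[, c("patient_id", "drug_class", "date",
                                        "amount_ddd")], gap_days = gap_days)
    }
    if (nrow(scan)) {
      cs <- scan$cov_start; cev <- scan$cov_end
      pid <- as.character(scan$patient_id)
      new_run <- c(TRUE, pid[-1] != pid[-length(pid)] |
                     cs[-1] > cev[-length(cev)] + 1e-9)
      rid <- cumsum(new_run)
      runs <- data.frame(patient_id = pid[new_run],
                         start = cs[new_run],
                         end = as.numeric(tapply(cev, rid, max)),
                         stringsAsFactors = FALSE)
      d <- whole_days(pmax(runs$start, w0), pmin(runs$end, w1))
      agg <- rowsum(d, runs$patient_id)
      drug_days[rownames(agg)] <- as.integer(agg[, 1])
    }
  }
  covered <- drug_days
  if (!is.null(hospital_stays) && nrow(hospital_stays) && bridge != "none" &&
      !is.null(era_info)) {
    st <- hospital_stays
    adm <- as_day(st$admission_date); dis <- as_day(st$discharge_date)
    sel <- dis > w0 & adm < w1 &
      as.character(st$patient_id) %in% era_info$patient_id
    if (any(sel)) {
      st_pid <- as.character(st$patient_id)[sel]
      adm <- adm[sel]; dis <- dis[sel]
      eras_by <- split(seq_len(nrow(era_info)), era_info$patient_id)
      runs_by <- if (!is.null(runs)) split(seq_len(nrow(runs)),
                                           runs$patient_id) else list()
      for (p in unique(st_pid)) {
        six <- which(st_pid == p)
        ei <- eras_by[[p]]
        ok <- if (bridge == "any_prior_era") {
          vapply(adm[six], function(a) any(era_info$start[ei] < a), logical(1))
        } else {
          vapply(adm[six], function(a)
            any(era_info$start[ei] < a & era_info$end[ei] > a), logical(1))
        }
        if (!any(ok)) next
        ri <- runs_by[[p]]
        iv <- merge_intervals(
          c(pmax(runs$start[ri], w0), pmax(adm[six][ok], w0)),
          c(pmin(runs$end[ri], w1), pmin(dis[six][ok], w1)))
        covered[p] <- covered_day_count(clip_intervals(iv, w0, w1))
      }
    }
  }
  pdc <- unname(covered) / wd
  out <- data.frame(patient_id = ids, covered_days = unname(covered),
                    pdc = pdc, category = categorize_pdc(pdc),
                    stringsAsFactors = FALSE)
  for (t in thresholds)
    out[[sprintf("high_at_%d", round(100 * t))]] <- pdc >= t
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one object; all study
#' constants (gap days, lookback, PDC cut-offs, control rules, matching
#' tolerances) are configurable here rather than hard-coded.  `scenario`
#' holds the synthetic-data parameters; when a pre-generated bundle is
#' passed to [run_pipeline()] the scenario is ignored.
#'
#' @param scenario a [claims_scenario()] (or list of its arguments).
#' @param classes drug classes to analyse (default `c("BP", "LIPID",
#'   "GLUCOSE")` intersected with the data).
#' @param ratio comparators per exposed (default 3).
#' @param gap_days,lookback_days,min_dispensations era/prevalence rules.
#' @param followup_days follow-up window length.
#' @param pdc_thresholds outcome thresholds; the second (0.75) is the main
#'   outcome, the others feed the sensitivity suite.
#' @param bridge,spillover PDC options (see [compute_pdc()]).
#' @param contact_rule,contact_caliper,age_tolerance matching tolerances
#'   (see [match_comparators()]).
#' @param adjustment_covariates covariate columns added to the main model.
#' @param strata list of stratified analyses: names are set-level
#'   variables, values are `"homogeneity"` or `"trend"`.
#' @param mcs_cutpoints comorbidity-score bin cut-points.
#' @param control_codes service-code map for the five diabetes controls.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = claims_scenario(),
                            classes = c("BP", "LIPID", "GLUCOSE"),
                            ratio = 3,
                            gap_days = 60, lookback_days = 730,
                            min_dispensations = 3, followup_days = 365,
                            pdc_thresholds = c(0.70, 0.75, 0.80),
                            bridge = "any_prior_era", spillover = TRUE,
                            contact_rule = "decile", contact_caliper = 10,
                            age_tolerance = 1,
                            adjustment_covariates = character(0),
                            strata = list(diagnosis = "homogeneity",
                                          gender = "homogeneity",
                                          age_class = "trend",
                                          mcs_category = "trend"),
                            mcs_cutpoints = c(1, 3, 5),
                            control_codes = default_control_codes()) {
  if (is.list(scenario) && !inherits(scenario, "claims_scenario"))
    scenario <- do.call(claims_scenario, scenario)
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments (with `scenario` a map of [claims_scenario()] arguments).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenario)) {
    if (!is.null(raw$scenario$drug_class_mix))
      raw$scenario$drug_class_mix <- unlist(raw$scenario$drug_class_mix)
    if (!is.null(raw$scenario$control_rates))
      raw$scenario$control_rates <- unlist(raw$scenario$control_rates)
  }
  do.call(pipeline_config, raw)
}

#' Run the full matched-cohort adherence pipeline
#'
#' Orchestrates simulate (unless a bundle is supplied) → drug eras →
#' eligibility → exposure ascertainment → 1:M matching → adherence →
#' covariates → conditional logistic analysis (main, stratified,
#' sensitivity) with balance diagnostics and a flow-count report, for each
#' requested drug class.  Fully deterministic given the scenario seed.
#'
#' @param config a [pipeline_config()], or a path to a YAML file for
#'   [read_pipeline_config()].
#' @param bundle optional pre-generated `claims_bundle`; when supplied the
#'   generator is skipped.
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV.
#' @param fit_strata set FALSE to skip stratified/sensitivity analyses.
#' @return object of class `pipeline_result`: per-class results
#'   (`members`, `main_fit`, `estimate`, `sensitivity`, `stratified`,
#'   `balance`, `pre_balance`) plus `manifest` and `flow`.
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL,
                         out_dir = NULL, fit_strata = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(bundle)) bundle <- simulate_claims(config$scenario)
  set.seed(config$scenario$seed + 1L)   # stages downstream of generation
  index_date <- config$scenario$index_date
  idx <- as_day(index_date)
  window <- followup_window(index_date, config$followup_days)
  classes <- intersect(config$classes,
                       unique(as.character(bundle$dispensations$drug_class)))
  mh <- bundle$mental_health_records
  mh_ids <- unique(as.character(mh$patient_id))
  results <- list()
  flow <- list()
  manifest <- list(seed = bundle$manifest$seed,
                   config_hash = bundle$manifest$config_hash,
                   version = as.character(utils::packageVersion("pdcmatch")),
                   stages = list())
  for (cl in classes) {
    stage <- list(class = cl)
    elig <- apply_eligibility(bundle, index_date, cl,
                              gap_days = config$gap_days,
                              lookback_days = config$lookback_days,
                              min_dispensations = config$min_dispensations,
                              followup_days = config$followup_days)
    stage$n_input <- attr(elig, "n_input")
    stage$n_eligible <- nrow(elig)
    excl <- attr(elig, "exclusions")
    # exposure from the mental-health registry
    has_mh <- elig$patient_id %in% mh_ids
    expo <- exposure_table(mh, index_date)
    hit <- match(elig$patient_id, expo$patient_id)
    expo_flag <- !is.na(hit)
    expo_dx <- expo$diagnosis_category[hit]
    elig$exposed <- as.integer(expo_flag)
    elig$diagnosis <- expo_dx
    exposed_df <- elig[expo_flag, , drop = FALSE]
    pool_df <- elig[!has_mh, , drop = FALSE]   # no mental-health record at all
    stage$n_exposed <- nrow(exposed_df)
    stage$n_pool <- nrow(pool_df)
    sets <- match_comparators(exposed_df, pool_df, ratio = config$ratio,
                              age_tolerance = config$age_tolerance,
                              contact_rule = config$contact_rule,
                              contact_caliper = config$contact_caliper)
    stage$n_sets <- if (nrow(sets)) max(sets$set_id) else 0L
    stage$n_unmatched_exposed <- length(attr(sets, "unmatched"))
    stage$n_members <- nrow(sets)
    members <- merge(sets, elig, by = "patient_id", sort = FALSE)
    members <- members[order(members$set_id, -members$exposed.x), ,
                       drop = FALSE]
    names(members)[names(members) == "exposed.x"] <- "exposed"
    members$exposed.y <- NULL
    # adherence outcomes
    adh <- pdc_table(bundle$dispensations, members$patient_id, cl, window,
                     hospital_stays = bundle$hospital_stays,
                     gap_days = config$gap_days, bridge = config$bridge,
                     spillover = config$spillover,
                     thresholds = config$pdc_thresholds)
    members <- cbind(members, adh[match(members$patient_id, adh$patient_id),
                                  -1, drop = FALSE])
    # baseline covariates
    cov <- derive_covariates(bundle, members$patient_id, index_date,
                             mcs_cutpoints = config$mcs_cutpoints,
                             lookback_days = config$lookback_days)
    members <- cbind(members, cov[match(members$patient_id, cov$patient_id),
                                  -1, drop = FALSE])
    members$age_class <- cut(members$age_at_index,
                             breaks = c(-Inf, 59, 69, 79, Inf),
                             labels = c("18-59", "60-69", "70-79", "80+"))
    rownames(members) <- NULL
    res <- list(class = cl, members = members, exclusions = excl)
    main_th <- sprintf("high_at_%d", round(100 * config$pdc_thresholds[2]))
    rhs <- paste(c("exposed", config$adjustment_covariates), collapse = " + ")
    f <- as.formula(paste(main_th, "~", rhs))
    fit <- tryCatch(clr(f, members, "set_id", quiet = TRUE),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      res$main_fit <- NULL
      res$error <- conditionMessage(fit)
    } else {
      res$main_fit <- fit
      res$estimate <- effect_estimate(fit, "exposed")
    }
    # clinical-control adherence for the antidiabetic class
    if (cl == "GLUCOSE") {
      prof <- controls_table(bundle$outpatient_services, members$patient_id,
                             window, config$control_codes)
      members$controls_high_4 <- prof$high_controls_at_4
      members$controls_high_3 <- prof$high_controls_at_3
      members$n_controls_satisfied <- prof$n_satisfied
      res$members <- members
      cfit <- tryCatch(clr(as.formula(paste("controls_high_4 ~", rhs)),
                           members, "set_id", quiet = TRUE),
                       error = function(e) NULL)
      if (!is.null(cfit)) {
        res$controls_fit <- cfit
        res$controls_estimate <- effect_estimate(cfit, "exposed")
      }
    }
    # balance before and after matching
    bal_vars <- c("gender_f", "age_at_index", "n_contacts")
    elig$gender_f <- as.integer(elig$gender == "F")
    members$gender_f <- as.integer(members$gender == "F")
    pre <- rbind(exposed_df, pool_df)
    pre$gender_f <- as.integer(pre$gender == "F")
    pre$exposed <- rep(c(1L, 0L), c(nrow(exposed_df), nrow(pool_df)))
    res$pre_balance <- balance_table(pre, bal_vars)
    res$balance <- balance_table(members, bal_vars)
    res$members <- members
    if (fit_strata && !is.null(res$main_fit)) {
      outs <- sprintf("high_at_%d", round(100 * config$pdc_thresholds))
      if (cl == "GLUCOSE" && !is.null(members$controls_high_4))
        outs <- c(outs, "controls_high_4", "controls_high_3")
      res$sensitivity <- sensitivity_suite(members, "set_id", outs,
                                           rhs = rhs)
      res$stratified <- list()
      for (sv in names(config$strata)) {
        if (!sv %in% names(members)) next
        est <- tryCatch(stratified_estimates(f, members, "set_id", sv),
                        error = function(e) NULL)
        if (is.null(est) || is.null(nrow(est)) || nrow(est) < 2) next
        est <- est[order(est$stratum), , drop = FALSE]
        test <- if (config$strata[[sv]] == "trend")
          tryCatch(trend_test(est$beta, est$se, seq_len(nrow(est))),
                   error = function(e) NULL)
        else
          tryCatch(homogeneity_test(est$beta, est$se),
                   error = function(e) NULL)
        res$stratified[[sv]] <- list(estimates = est, test = test,
                                     type = config$strata[[sv]])
      }
    }
    results[[cl]] <- res
    flow[[cl]] <- data.frame(drug_class = cl,
                             criterion = excl$criterion,
                             removed = excl$removed)
    manifest$stages[[cl]] <- stage
  }
  out <- list(results = results, manifest = manifest,
              flow = do.call(rbind, c(flow, list(make.row.names = FALSE))),
              config = config)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

# Vectorised exposure ascertainment over the whole mental-health registry:
# one row per patient with an episode open at the index date, carrying the
# most severe active diagnosis (schizophrenia > bipolar > personality >
# depression).
exposure_table <- function(mh, index_date) {
  rank <- c(schizophrenia = 1, `bipolar disorder` = 2,
            `personality disorder` = 3, depression = 4)
  if (is.null(mh) || !nrow(mh))
    return(data.frame(patient_id = character(0),
                      diagnosis_category = character(0)))
  idx <- as_day(index_date)
  open <- as_day(mh$episode_open); close <- as_day(mh$episode_close)
  dx <- as.character(mh$diagnosis)
  active <- open <= idx & (!is.finite(close) | close > idx) & dx %in% names(rank)
  active[is.na(active)] <- FALSE
  if (!any(active))
    return(data.frame(patient_id = character(0),
                      diagnosis_category = character(0)))
  pid <- as.character(mh$patient_id)[active]
  r <- unname(rank[dx[active]])
  best <- tapply(r, pid, min)
  inv <- names(rank)
  data.frame(patient_id = names(best),
             diagnosis_category = inv[as.integer(best)],
             stringsAsFactors = FALSE)
}

# Batch clinical-control scoring (one warning for unknown codes).
controls_table <- function(services, patient_ids, window, code_map) {
  ids <- as.character(patient_ids)
  controls <- c("hba1c", "lipid_profile", "serum_creatinine",
                "urine_albumin", "eye_exam")
  need <- c(hba1c = 2L, lipid_profile = 1L, serum_creatinine = 1L,
            urine_albumin = 1L, eye_exam = 1L)
  lut <- rep(names(code_map), lengths(code_map))
  names(lut) <- unlist(code_map, use.names = FALSE)
  w0 <- as_day(window$start); w1 <- as_day(window$end)
  day <- as_day(services$date)
  sel <- day >= w0 & day < w1 & as.character(services$patient_id) %in% ids &
    as.character(services$service_code) %in% names(lut)
  sv <- services[sel, , drop = FALSE]
  cnt <- matrix(0L, length(ids), 5, dimnames = list(ids, controls))
  if (nrow(sv)) {
    tb <- table(factor(as.character(sv$patient_id), levels = ids),
                factor(lut[as.character(sv$service_code)], levels = controls))
    cnt <- unclass(tb)
  }
  sat <- sweep(cnt, 2, need[controls], ">=")
  ns <- rowSums(sat)
  data.frame(patient_id = ids, n_satisfied = as.integer(ns),
             high_controls_at_4 = ns >= 4, high_controls_at_3 = ns >= 3,
             stringsAsFactors = FALSE)
}

#' Flow-count report of eligibility and matching
#'
#' Tabulates, per drug class, the number of patients removed by each
#' eligibility criterion and the retained counts; totals reconcile with the
#' manifest (input = retained + removals).
#'
#' @param x a `pipeline_result`.
#' @return data frame with `drug_class`, `criterion`, `removed`.
#' @export
flow_report <- function(x) {
  stopifnot(inherits(x, "pipeline_result"))
  x$flow
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Matched-cohort adherence pipeline\n")
  for (cl in names(x$results)) {
    r <- x$results[[cl]]
    st <- x$manifest$stages[[cl]]
    cat(sprintf("\n[%s] %d candidates -> %d eligible; %d exposed, %d matched sets\n",
                cl, st$n_input, st$n_eligible, st$n_exposed, st$n_sets))
    if (!is.null(r$estimate)) {
      pv <- percent_variation(r$estimate)
      cat(sprintf("  high drug adherence: (OR-1)x100 = %+.1f%% (%+.1f to %+.1f)\n",
                  pv$pct, pv$ci[1], pv$ci[2]))
    }
    if (!is.null(r$controls_estimate)) {
      pv <- percent_variation(r$controls_estimate)
      cat(sprintf("  high clinical controls: (OR-1)x100 = %+.1f%% (%+.1f to %+.1f)\n",
                  pv$pct, pv$ci[1], pv$ci[2]))
    }
  }
  invisible(x)
}

write_pipeline_result <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(x$flow, file.path(out_dir, "flow_report.csv"), row.names = FALSE)
  est_rows <- list()
  for (cl in names(x$results)) {
    r <- x$results[[cl]]
    keep <- !vapply(r$members, is.list, logical(1))
    write.csv(r$members[, keep, drop = FALSE],
              file.path(out_dir, paste0("matched_members_", cl, ".csv")),
              row.names = FALSE)
    write.csv(r$balance, file.path(out_dir, paste0("balance_", cl, ".csv")),
              row.names = FALSE)
    if (!is.null(r$sensitivity))
      write.csv(r$sensitivity,
                file.path(out_dir, paste0("sensitivity_", cl, ".csv")),
                row.names = FALSE)
    if (!is.null(r$estimate)) {
      e <- r$estimate
      est_rows[[paste0(cl, "_drug")]] <-
        data.frame(drug_class = cl, outcome = "high_drug_adherence",
                   or = e$or_value, ci_low = e$ci95[1], ci_high = e$ci95[2],
                   pct = e$pct_variation, pct_low = e$pct_ci[1],
                   pct_high = e$pct_ci[2], n_sets = e$n_sets_informative)
    }
    if (!is.null(r$controls_estimate)) {
      e <- r$controls_estimate
      est_rows[[paste0(cl, "_controls")]] <-
        data.frame(drug_class = cl, outcome = "high_clinical_controls",
                   or = e$or_value, ci_low = e$ci95[1], ci_high = e$ci95[2],
                   pct = e$pct_variation, pct_low = e$pct_ci[1],
                   pct_high = e$pct_ci[2], n_sets = e$n_sets_informative)
    }
  }
  if (length(est_rows))
    write.csv(do.call(rbind, c(est_rows, list(make.row.names = FALSE))),
              file.path(out_dir, "effect_estimates.csv"), row.names = FALSE)
  yaml::write_yaml(list(seed = x$manifest$seed,
                        config_hash = x$manifest$config_hash,
                        version = x$manifest$version,
                        stages = x$manifest$stages),
                   file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
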