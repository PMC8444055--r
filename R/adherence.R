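#' One-year follow-up window
#'
#' @param index_date cohort entry date; the window is the half-open interval
#'   `[index_date, index_date + days)`.
#' @param days window length in days (default 365, one year of follow-up).
#' @return list with `start`, `end` (Date) and `days`.
#' @export
followup_window <- function(index_date, days = 365) {
  idx <- as_day(index_date)
  if (!is.finite(idx)) stop_config("index_date must be a valid date")
  list(start = as_date(idx), end = as_date(idx + days), days = as.integer(days))
}

#' Proportion of days covered with hospital-stay bridging
#'
#' Computes drug adherence for one patient and drug class over a follow-up
#' window as the proportion of days covered (PDC): the number of whole days
#' on which the drug was available, divided by the window length.  The
#' duration of each dispensation is its dispensed amount divided by the
#' defined daily dose (`amount_ddd`, in days of supply); early refills
#' stockpile (see [build_eras()]), and supply dispensed before the window
#' that spills into it counts by default.
#'
#' Because in-hospital drug use is not observed in out-patient dispensing
#' claims (immeasurable time), days spent in hospital are counted as covered
#' for patients whose therapeutic regimen was observed before the admission:
#' by default, any drug era of this class starting before the admission date
#' qualifies; with `bridge = "active"` the era's coverage must still be
#' running at admission.
#'
#' @param dispensations dispensations of one patient and drug class (columns
#'   `date`, `amount_ddd`), sorted by date; dispensations before the window
#'   are used for era chaining and spillover.
#' @param window a [followup_window()].
#' @param hospital_stays optional data frame with columns `admission_date`
#'   and `discharge_date`; the stay occupies the half-open day interval
#'   `[admission, discharge)`.
#' @param gap_days era-chaining gap passed to [build_eras()].
#' @param bridge `"any_prior_era"` (default) or `"active"`; `"none"`
#'   disables bridging.
#' @param spillover count pre-window supply spilling into the window
#'   (default TRUE).
#' @param thresholds PDC cut-offs at which `high_at_*` flags are computed.
#' @return An object of class `adherence_result`: list with `covered_days`,
#'   `window_days`, `pdc`, `category` (see [categorize_pdc()]) and logical
#'   flags `high_at_70`, `high_at_75`, `high_at_80`.
#' @examples
#' w <- followup_window("2017-01-01")
#' d <- data.frame(date = as.Date("2017-01-01"), amount_ddd = 200)
#' compute_pdc(d, w)  # 200/365 covered, intermediate adherence
#' @export
compute_pdc <- function(dispensations, window, hospital_stays = NULL,
                        gap_days = 60, bridge = c("any_prior_era", "active", "none"),
                        spillover = TRUE, thresholds = c(0.70, 0.75, 0.80)) {
  bridge <- match.arg(bridge)
  w0 <- as_day(window$start); w1 <- as_day(window$end)
  iv <- list(start = numeric(0), end = numeric(0))
  era_starts <- numeric(0); era_ends <- numeric(0)
  if (!is.null(dispensations) && nrow(dispensations)) {
    # bridging eligibility always looks at the full dispensing history
    eras <- build_eras(dispensations, gap_days = gap_days)
    era_starts <- as_day(eras$start)
    era_ends <- as_day(eras$coverage_end)
    cov_src <- dispensations
    if (!spillover)   # numerator from in-window dispensations only
      cov_src <- dispensations[as_day(dispensations$date) >= w0, ,
                               drop = FALSE]
    if (nrow(cov_src)) {
      cov <- attr(build_eras(cov_src, gap_days = gap_days), "coverage")
      iv <- merge_intervals(cov$start, cov$end)
    }
  }
  drug_iv <- clip_intervals(iv, w0, w1)
  all_iv <- drug_iv
  if (!is.null(hospital_stays) && nrow(hospital_stays) && bridge != "none") {
    adm <- as_day(hospital_stays$admission_date)
    dis <- as_day(hospital_stays$discharge_date)
    if (any(!is.finite(adm)) || any(!is.finite(dis)) || any(dis < adm))
      stop("hospital stays must have valid admission <= discharge dates")
    ok <- if (bridge == "any_prior_era") {
      vapply(adm, function(a) any(era_starts < a), logical(1))
    } else {
      vapply(adm, function(a) any(era_starts < a & era_ends > a), logical(1))
    }
    if (any(ok)) {
      all_iv <- merge_intervals(c(all_iv$start, pmax(adm[ok], w0)),
                                c(all_iv$end, pmin(dis[ok], w1)))
      all_iv <- clip_intervals(all_iv, w0, w1)
    }
  }
  covered <- covered_day_count(all_iv)
  wd <- as.integer(w1 - w0)
  pdc <- covered / wd
  out <- list(covered_days = covered, window_days = wd, pdc = pdc,
              category = categorize_pdc(pdc))
  for (t in thresholds)
    out[[sprintf("high_at_%d", round(100 * t))]] <- pdc >= t
  class(out) <- "adherence_result"
  out
}

#' @export
print.adherence_result <- function(x, ...) {
  cat(sprintf("PDC = %.3f (%d/%d days covered), category: %s\n",
              x$pdc, x$covered_days, x$window_days, x$category))
  invisible(x)
}

#' Four-level adherence category from a PDC value
#'
#' Very low: PDC in `[0, 0.25]`; low: `(0.25, 0.50]`; intermediate:
#' `(0.50, 0.75)`; high: `[0.75, 1]`.  The integer-percent shorthand
#' "26-50%" etc. is read as these half-open intervals on the continuous
#' scale, so that a PDC of exactly 75% is high and exactly 50% is low.
#'
#' @param pdc numeric vector in `[0, 1]`.
#' @return factor with levels `very_low`, `low`, `intermediate`, `high`.
#' @export
categorize_pdc <- function(pdc) {
  pdc <- as.numeric(pdc)
  if (any(!is.finite(pdc)) || any(pdc < 0 | pdc > 1))
    stop_config("pdc must lie in [0, 1]")
  lev <- c("very_low", "low", "intermediate", "high")
  out <- ifelse(pdc >= 0.75, "high",
         ifelse(pdc > 0.50, "intermediate",
         ifelse(pdc > 0.25, "low", "very_low")))
  factor(out, levels = lev)
}

#' Score the diabetes clinical-control recommendation bundle
#'
#' Five recommended annual controls for patients on glucose-lowering
#' therapy: glycated haemoglobin (satisfied by at least two assays in the
#' year) plus lipid profile, serum creatinine, urine albumin excretion and
#' dilated eye examination (each satisfied by at least one).  "High"
#' clinical-control adherence means at least four of the five satisfied
#' (main definition) or at least three (sensitivity definition).
#'
#' @param services out-patient service records of one patient (columns
#'   `date` and `service_code`).
#' @param window a [followup_window()]; only services inside it count.
#' @param code_map named list mapping each control
#'   (`hba1c`, `lipid_profile`, `serum_creatinine`, `urine_albumin`,
#'   `eye_exam`) to the character vector of service codes that count towards
#'   it.  Codes not matching any control are skipped with a warning.
#' @return An object of class `control_profile`: list with per-control
#'   `counts`, logical `satisfied`, `n_satisfied`, and flags
#'   `high_controls_at_4`, `high_controls_at_3`.
#' @export
assess_clinical_controls <- function(services, window,
                                     code_map = default_control_codes()) {
  controls <- c("hba1c", "lipid_profile", "serum_creatinine",
                "urine_albumin", "eye_exam")
  if (!all(controls %in% names(code_map)))
    stop_config("code_map must name all five controls: ",
                paste(setdiff(controls, names(code_map)), collapse = ", "))
  counts <- setNames(integer(length(controls)), controls)
  if (!is.null(services) && nrow(services)) {
    day <- as_day(services$date)
    w0 <- as_day(window$start); w1 <- as_day(window$end)
    inw <- day >= w0 & day < w1
    code <- as.character(services$service_code)[inw]
    lut <- rep(names(code_map), lengths(code_map))
    names(lut) <- unlist(code_map, use.names = FALSE)
    hit <- lut[code]
    if (anyNA(hit)) {
      warning("skipping ", sum(is.na(hit)),
              " service record(s) with unrecognised codes: ",
              paste(unique(code[is.na(hit)]), collapse = ", "))
      hit <- hit[!is.na(hit)]
    }
    tab <- table(factor(hit, levels = controls))
    counts[controls] <- as.integer(tab)
  }
  required <- c(hba1c = 2L, lipid_profile = 1L, serum_creatinine = 1L,
                urine_albumin = 1L, eye_exam = 1L)
  satisfied <- counts >= required[controls]
  out <- list(counts = counts, satisfied = satisfied,
              n_satisfied = sum(satisfied),
              high_controls_at_4 = sum(satisfied) >= 4L,
              high_controls_at_3 = sum(satisfied) >= 3L)
  class(out) <- "control_profile"
  out
}

#' Default service-code map for the five diabetes controls
#'
#' Synthetic-data codes; real deployments supply their regional codelists.
#' @return named list of character vectors.
#' @export
default_control_codes <- function() {
  list(hba1c = "HBA1C",
       lipid_profile = c("CHOL_TOT", "CHOL_HDL", "TRIGLYCERIDES"),
       serum_creatinine = "CREATININE",
       urine_albumin = "URINE_ALBUMIN",
       eye_exam = "EYE_EXAM")
}

#' @export
print.control_profile <- function(x, ...) {
  cat("Clinical controls satisfied:", x$n_satisfied, "of 5",
      sprintf("(high at >=4: %s, at >=3: %s)\n",
              x$high_controls_at_4, x$high_controls_at_3))
  invisible(x)
}
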