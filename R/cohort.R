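#' Count healthcare contacts in the pre-index lookback
#'
#' Contacts with the health system are drug dispensations (any class),
#' hospital admissions and out-patient visits/procedures dated in
#' `[index_date - lookback_days, index_date)`.
#'
#' @param tables list with `dispensations`, `hospital_stays`,
#'   `outpatient_services` (any may be NULL).
#' @param index_date index date.
#' @param lookback_days lookback length (default 730).
#' @return named integer vector of contact counts per patient id (patients
#'   with no events are absent; treat as zero).
#' @export
count_contacts <- function(tables, index_date, lookback_days = 730) {
  idx <- as_day(index_date); lo <- idx - lookback_days
  ids <- character(0)
  grab <- function(tab, datecol) {
    if (is.null(tab) || !nrow(tab)) return(character(0))
    day <- as_day(tab[[datecol]])
    as.character(tab$patient_id[day >= lo & day < idx])
  }
  ids <- c(grab(tables$dispensations, "date"),
           grab(tables$hospital_stays, "admission_date"),
           grab(tables$outpatient_services, "date"))
  tab <- table(ids)
  setNames(as.integer(tab), names(tab))
}

#' Screen patients for cohort eligibility with flow accounting
#'
#' Sequentially applies the eligibility criteria for one drug class:
#' age 18+ at the index date, at least `residency_years` of residency
#' before it, prevalent use of the class (a chain of at least
#' `min_dispensations` dispensations in the `lookback_days` pre-index
#' window, per [is_prevalent_user()]), and at least one year of post-index
#' observation (no death or emigration within `followup_days`).  Records
#' without a birth date are rejected with a logged reason.
#'
#' @param tables list of registry tables: `patients`, `dispensations`
#'   (with `drug_class`), `hospital_stays`, `outpatient_services`,
#'   `mental_health_records`.
#' @param index_date cohort entry date.
#' @param drug_class class to screen for (e.g. `"BP"`).
#' @param gap_days,lookback_days,min_dispensations era and prevalence
#'   parameters (defaults 60, 730, 3).
#' @param followup_days required post-index observation (default 365).
#' @param residency_years required pre-index residency (default 2).
#' @param require_active passed to [is_prevalent_user()].
#' @return data frame of eligible patients (`patient_id`, `gender`,
#'   `age_at_index`, `n_contacts`) with attribute `"exclusions"`: a data
#'   frame of per-criterion removal counts, in application order, whose
#'   total plus the retained count equals the input count.
#' @export
apply_eligibility <- function(tables, index_date, drug_class,
                              gap_days = 60, lookback_days = 730,
                              min_dispensations = 3, followup_days = 365,
                              residency_years = 2, require_active = FALSE) {
  idx <- as_day(index_date)
  pats <- tables$patients
  disp <- tables$dispensations
  disp <- disp[disp$drug_class == drug_class, , drop = FALSE]
  candidates <- pats[as.character(pats$patient_id) %in%
                       as.character(disp$patient_id), , drop = FALSE]
  steps <- list()
  note <- function(label, keep) {
    steps[[length(steps) + 1L]] <<- data.frame(criterion = label,
                                               removed = sum(!keep))
    candidates[keep, , drop = FALSE]
  }
  n_input <- nrow(candidates)
  bday <- as_day(candidates$birth_date)
  candidates <- note("missing birth date", is.finite(bday))
  bday <- as_day(candidates$birth_date)
  age <- floor((idx - bday) / 365.25)
  candidates <- note("aged under 18 at index", age >= 18)
  res <- col_days(candidates, "residency_start")
  candidates <- note(sprintf("resident for under %g years", residency_years),
                     is.finite(res) & res <= idx - round(365.25 * residency_years))
  # prevalent use of the class in the lookback window
  scan <- era_scan_table(disp[as.character(disp$patient_id) %in%
                                as.character(candidates$patient_id), ,
                              drop = FALSE], gap_days = gap_days)
  prev_ids <- prevalent_ids(scan, idx, lookback_days, min_dispensations,
                            require_active)
  candidates <- note(sprintf("fewer than %d chained dispensations in lookback",
                             min_dispensations),
                     as.character(candidates$patient_id) %in% prev_ids)
  death <- col_days(candidates, "death_date")
  emig <- col_days(candidates, "emigration_date")
  gone <- (is.finite(death) & death < idx + followup_days) |
    (is.finite(emig) & emig < idx + followup_days)
  gone[is.na(gone)] <- FALSE
  candidates <- note("died or emigrated within 1 year of index", !gone)
  contacts <- count_contacts(tables, index_date, lookback_days)
  out <- data.frame(
    patient_id = as.character(candidates$patient_id),
    gender = as.character(candidates$gender),
    age_at_index = floor((idx - as_day(candidates$birth_date)) / 365.25),
    stringsAsFactors = FALSE
  )
  out$n_contacts <- unname(contacts[out$patient_id])
  out$n_contacts[is.na(out$n_contacts)] <- 0L
  excl <- do.call(rbind, steps)
  excl <- rbind(excl, data.frame(criterion = "retained", removed = nrow(out)))
  attr(out, "exclusions") <- excl
  attr(out, "n_input") <- n_input
  out
}

col_days <- function(df, col) {
  if (is.null(df[[col]])) rep(NA_real_, nrow(df)) else as_day(df[[col]])
}

# Patient ids with a qualifying chain, from an era_scan_table() result.
prevalent_ids <- function(scan, idx, lookback_days, min_dispensations,
                          require_active = FALSE) {
  if (!nrow(scan)) return(character(0))
  inw <- scan$day >= idx - lookback_days & scan$day < idx
  if (require_active) {
    era_end <- ave(scan$cov_end, scan$era, FUN = max)
    inw <- inw & era_end >= idx
  }
  cnt <- rowsum(as.integer(inw), scan$era, reorder = FALSE)
  qual_era <- as.integer(rownames(cnt))[cnt[, 1] >= min_dispensations]
  unique(as.character(scan$patient_id[scan$era %in% qual_era]))
}

#' Ascertain exposure from mental-health registry records
#'
#' A patient is exposed when a care episode for one of the four severe
#' mental illness diagnoses (depression, schizophrenia, bipolar disorder,
#' personality disorder) is open at the index date: episode opened on or
#' before the index date and not closed by it (close date absent or after
#' the index).  When several episodes are open, the reported diagnosis
#' category follows the severity ranking schizophrenia > bipolar disorder >
#' personality disorder > depression.
#'
#' @param mh_records records for one patient (columns `diagnosis`,
#'   `episode_open`, `episode_close`).
#' @param index_date index date.
#' @return list with `exposed` (logical) and `diagnosis_category`
#'   (character or NA).
#' @export
ascertain_exposure <- function(mh_records, index_date) {
  rank <- c(schizophrenia = 1, `bipolar disorder` = 2,
            `personality disorder` = 3, depression = 4)
  if (is.null(mh_records) || !nrow(mh_records))
    return(list(exposed = FALSE, diagnosis_category = NA_character_))
  idx <- as_day(index_date)
  open <- as_day(mh_records$episode_open)
  close <- as_day(mh_records$episode_close)
  dx <- as.character(mh_records$diagnosis)
  active <- open <= idx & (!is.finite(close) | close > idx) & dx %in% names(rank)
  active[is.na(active)] <- FALSE
  if (!any(active)) return(list(exposed = FALSE,
                                diagnosis_category = NA_character_))
  dx_active <- dx[active]
  list(exposed = TRUE,
       diagnosis_category = dx_active[which.min(rank[dx_active])])
}

#' Randomly match comparators to exposed patients
#'
#' For each exposed patient, up to `ratio` comparators are sampled without
#' replacement from the unexposed pool among those with the same gender,
#' age at index within plus/minus 1 year, and healthcare-contact volume in
#' the same decile of the pool's contact distribution (or within a caliper,
#' see `contact_rule`).  Exposed patients are processed in seeded random
#' order; exposed with no eligible comparator are dropped and recorded.
#'
#' @param exposed data frame of exposed patients (`patient_id`, `gender`,
#'   `age_at_index`, `n_contacts`).
#' @param pool data frame of candidate comparators (same columns); must not
#'   contain exposed patients nor anyone with a mental-health record.
#' @param ratio comparators per exposed (default 3).
#' @param age_tolerance maximum age difference in years (default 1).
#' @param contact_rule `"decile"` (equal decile of the pool contact
#'   distribution, the default) or `"caliper"`.
#' @param contact_caliper absolute contact-count tolerance under
#'   `"caliper"` (default 10).
#' @param seed optional integer seed for the processing order and sampling.
#' @return data frame of class `matched_sets`: one row per member with
#'   `set_id`, `patient_id`, `exposed` (1/0); attribute `"unmatched"` lists
#'   exposed ids dropped for lack of comparators.
#' @export
match_comparators <- function(exposed, pool, ratio = 3, age_tolerance = 1,
                              contact_rule = c("decile", "caliper"),
                              contact_caliper = 10, seed = NULL) {
  contact_rule <- match.arg(contact_rule)
  if (ratio < 1) stop_config("ratio must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_pool <- nrow(pool)
  if (contact_rule == "decile") {
    br <- unique(quantile(pool$n_contacts, probs = seq(0.1, 0.9, by = 0.1),
                          type = 7, names = FALSE))
    pool_bin <- findInterval(pool$n_contacts, br)
    exp_bin <- findInterval(exposed$n_contacts, br)
  } else {
    pool_bin <- rep(0L, n_pool)
    exp_bin <- rep(0L, nrow(exposed))
  }
  # index pool by gender x contact-bin x integer age for fast lookup
  key <- paste(pool$gender, pool_bin, floor(pool$age_at_index), sep = "|")
  pool_by_key <- split(seq_len(n_pool), key)
  used <- logical(n_pool)
  order_exposed <- sample.int(nrow(exposed))
  sets <- vector("list", nrow(exposed))
  unmatched <- character(0)
  for (i in order_exposed) {
    ages <- (floor(exposed$age_at_index[i]) - age_tolerance):
      (floor(exposed$age_at_index[i]) + age_tolerance)
    cand <- unlist(pool_by_key[paste(exposed$gender[i], exp_bin[i], ages,
                                     sep = "|")], use.names = FALSE)
    if (length(cand)) {
      cand <- cand[!used[cand] &
                     abs(pool$age_at_index[cand] - exposed$age_at_index[i]) <=
                       age_tolerance]
      if (contact_rule == "caliper")
        cand <- cand[abs(pool$n_contacts[cand] - exposed$n_contacts[i]) <=
                       contact_caliper]
    }
    if (!length(cand)) {
      unmatched <- c(unmatched, as.character(exposed$patient_id[i]))
      next
    }
    take <- if (length(cand) <= ratio) cand else
      cand[sample.int(length(cand), ratio)]
    used[take] <- TRUE
    sets[[i]] <- data.frame(
      patient_id = c(as.character(exposed$patient_id[i]),
                     as.character(pool$patient_id[take])),
      exposed = c(1L, rep.int(0L, length(take))),
      stringsAsFactors = FALSE)
  }
  keep <- !vapply(sets, is.null, logical(1))
  sets <- sets[keep]
  if (!length(sets)) {
    out <- data.frame(set_id = integer(0), patient_id = character(0),
                      exposed = integer(0))
  } else {
    out <- do.call(rbind, sets)
    out <- data.frame(set_id = rep(seq_along(sets),
                                   vapply(sets, nrow, integer(1))),
                      out, stringsAsFactors = FALSE)
  }
  attr(out, "unmatched") <- unmatched
  class(out) <- c("matched_sets", "data.frame")
  out
}

#' Absolute standardised difference between two groups
#'
#' Binary: `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`.
#' Continuous: `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`.
#' An ASD below 0.10 is conventionally treated as negligible imbalance.
#'
#' @param values_exposed,values_reference numeric (or logical) vectors.
#' @param type `"binary"` or `"continuous"`; guessed from the data when
#'   missing.
#' @return non-negative number; `Inf` when the pooled variance is zero but
#'   the means differ, 0 when both are identical point masses.
#' @export
standardized_difference <- function(values_exposed, values_reference,
                                    type = c("auto", "binary", "continuous")) {
  type <- match.arg(type)
  x <- as.numeric(values_exposed); yv <- as.numeric(values_reference)
  if (!length(x) || !length(yv)) stop_config("groups must be non-empty")
  if (type == "auto")
    type <- if (all(c(x, yv) %in% c(0, 1))) "binary" else "continuous"
  if (type == "binary") {
    p1 <- mean(x); p2 <- mean(yv)
    denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
    num <- abs(p1 - p2)
  } else {
    denom <- sqrt((stats::var(x) + stats::var(yv)) / 2)
    num <- abs(mean(x) - mean(yv))
  }
  if (is.na(denom)) return(NA_real_)   # undefined spread (singleton group)
  if (denom == 0) return(if (num == 0) 0 else Inf)
  num / denom
}

#' Covariate balance table for matched data
#'
#' @param data member-level data with an `exposed` column.
#' @param covariates character vector of covariate columns.
#' @return data frame with `covariate`, `asd`, and `flagged`
#'   (`asd >= 0.10`).
#' @export
balance_table <- function(data, covariates) {
  asd <- vapply(covariates, function(v)
    standardized_difference(data[[v]][data$exposed == 1],
                            data[[v]][data$exposed == 0]), numeric(1))
  data.frame(covariate = covariates, asd = unname(asd),
             flagged = unname(asd) >= 0.10)
}

#' Derive baseline covariates from claims over the pre-index lookback
#'
#' Boolean comorbidity/cotreatment flags are set when any qualifying event
#' (hospital diagnosis or drug dispensation matching the configured
#' codelist) occurs in the 2 years before the index date; the numeric
#' comorbidity score (`mcs_score` column of the patients table) is binned
#' into categories at the configured cut-points, with a score exactly at a
#' boundary assigned to the lower category.
#'
#' @param tables registry tables (see [apply_eligibility()]).
#' @param patient_ids ids to derive covariates for.
#' @param index_date index date.
#' @param codelists named list; each element is a list with `table`
#'   (`"dispensations"` or `"hospital_stays"`) and `codes` (character
#'   vector matched against `drug_class` or `diagnosis`).
#' @param mcs_cutpoints increasing numeric cut-points for the comorbidity
#'   score categories (default `c(1, 3, 5)`, giving 4 categories).
#' @param lookback_days lookback (default 730).
#' @return data frame: `patient_id`, one logical column per codelist, and
#'   `mcs_category` (integer, 1 = best clinical profile).
#' @export
derive_covariates <- function(tables, patient_ids, index_date,
                              codelists = default_codelists(),
                              mcs_cutpoints = c(1, 3, 5),
                              lookback_days = 730) {
  if (is.null(codelists)) stop_config("codelists configuration is required")
  idx <- as_day(index_date); lo <- idx - lookback_days
  ids <- as.character(patient_ids)
  out <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
  for (nm in names(codelists)) {
    cfg <- codelists[[nm]]
    tab <- tables[[cfg$table]]
    hit <- character(0)
    if (!is.null(tab) && nrow(tab)) {
      datecol <- if (cfg$table == "hospital_stays") "admission_date" else "date"
      codecol <- if (cfg$table == "hospital_stays") "diagnosis" else "drug_class"
      day <- as_day(tab[[datecol]])
      sel <- day >= lo & day < idx & as.character(tab[[codecol]]) %in% cfg$codes
      hit <- unique(as.character(tab$patient_id[sel]))
    }
    out[[nm]] <- ids %in% hit
  }
  if (!is.null(tables$patients$mcs_score)) {
    score <- tables$patients$mcs_score[match(ids,
                                             as.character(tables$patients$patient_id))]
    # boundary scores fall in the lower category
    out$mcs_category <- 1L + vapply(score, function(s)
      if (is.na(s)) NA_integer_ else sum(mcs_cutpoints < s), integer(1))
  }
  out
}

#' Default comorbidity/cotreatment codelists for the synthetic schema
#'
#' Real deployments supply their own ICD-9/ATC codelists; these names match
#' the codes emitted by [simulate_claims()].
#' @return named list of codelist configurations.
#' @export
default_codelists <- function() {
  list(nsaid = list(table = "dispensations", codes = "NSAID"),
       antithrombotic = list(table = "dispensations", codes = "ANTITHROMBOTIC"),
       respiratory_drug = list(table = "dispensations", codes = "RESP"),
       cardiovascular_disease = list(table = "hospital_stays",
                                     codes = "CARDIOVASCULAR"),
       renal_disease = list(table = "hospital_stays", codes = "RENAL"))
}
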