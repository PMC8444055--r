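#' Chain dispensations of one patient-drug stream into drug eras
#'
#' A drug era is a maximal run of dispensations in which each dispensation
#' begins no more than `gap_days` after the running coverage end of the
#' previous ones.  Supply stockpiles: an early refill extends coverage by its
#' full duration (one day of drug per defined daily dose, DDD, dispensed), so
#' the coverage end after dispensation *i* is
#' `max(date_i, previous end) + amount_ddd_i`.  A dispensation dated exactly
#' `gap_days` after the coverage end still chains; one day later opens a new
#' era.
#'
#' @param dispensations data frame with columns `date` (Date or ISO-8601
#'   character) and `amount_ddd` (positive; days of supply), sorted by date.
#'   Rows must belong to a single patient and drug class.
#' @param gap_days maximum permissible gap, in days, between the coverage end
#'   of one dispensation and the start of the next within an era (default 60).
#' @return A data frame of class `drug_era_table`, one row per era, with
#'   columns `start`, `coverage_end` (Date; half-open interval
#'   `[start, coverage_end)`), `n_dispensations`, and a list column
#'   `member_dispensations` holding the row indices of the era's members.
#'   The attribute `"coverage"` stores the per-dispensation effective
#'   coverage intervals (used for proportion-of-days-covered computation);
#'   within an era these are disjoint and ordered.
#' @examples
#' d <- data.frame(date = as.Date("2017-01-01") + c(0, 25, 100),
#'                 amount_ddd = c(30, 30, 30))
#' build_eras(d)  # one era covering [day 0, day 130)
#' @seealso [is_prevalent_user()], [compute_pdc()]
#' @export
build_eras <- function(dispensations, gap_days = 60) {
  stopifnot(is.data.frame(dispensations))
  if (gap_days < 0) stop_config("gap_days must be >= 0")
  n <- nrow(dispensations)
  if (n == 0L) {
    out <- data.frame(start = as_date(numeric(0)),
                      coverage_end = as_date(numeric(0)),
                      n_dispensations = integer(0))
    out$member_dispensations <- list()
    attr(out, "coverage") <- list(start = numeric(0), end = numeric(0),
                                  era = integer(0))
    class(out) <- c("drug_era_table", "data.frame")
    return(out)
  }
  day <- as_day(dispensations$date)
  amt <- as.numeric(dispensations$amount_ddd)
  if (any(!is.finite(day))) stop("dispensation dates must be valid dates")
  if (any(diff(day) < 0)) stop("dispensations must be sorted by date")
  if (any(!(amt > 0))) stop("amount_ddd must be positive")
  scan <- era_scan_cpp(day, amt, rep.int(1L, n), gap_days)
  era <- scan$era
  first <- !duplicated(era)
  out <- data.frame(
    start = as_date(day[first]),
    coverage_end = as_date(tapply(scan$cov_end, era, max)),
    n_dispensations = as.integer(tabulate(era))
  )
  out$member_dispensations <- split(seq_len(n), era)
  attr(out, "coverage") <- list(start = scan$cov_start, end = scan$cov_end,
                                era = era)
  class(out) <- c("drug_era_table", "data.frame")
  out
}

#' Decide prevalent-user status at an index date
#'
#' A patient is a prevalent user of a drug class when some single era
#' contains at least `min_dispensations` dispensations all dated inside the
#' lookback window `[index_date - lookback_days, index_date)` — i.e. at
#' least three consecutive (chained) dispensations in the two years before
#' cohort entry, under the defaults.
#'
#' By default the chain only needs to exist inside the lookback window; set
#' `require_active = TRUE` to additionally require the qualifying era's
#' coverage to reach the index date (era still active at entry).
#'
#' @param eras result of [build_eras()] together with its originating
#'   dispensation table (needed for member dates), or the dispensation table
#'   itself (eras are then built with `gap_days`).
#' @param dispensations the dispensation table the eras were built from;
#'   ignored when `eras` is itself a dispensation table.
#' @param index_date cohort entry date.
#' @param lookback_days length of the pre-index window (default 730).
#' @param min_dispensations minimum chain length (default 3).
#' @param require_active if TRUE, the qualifying era must still cover the
#'   index date.
#' @param gap_days passed to [build_eras()] when eras must be built here.
#' @return logical scalar.
#' @export
is_prevalent_user <- function(eras, dispensations = NULL, index_date,
                              lookback_days = 730, min_dispensations = 3,
                              require_active = FALSE, gap_days = 60) {
  if (!inherits(eras, "drug_era_table")) {
    dispensations <- eras
    eras <- build_eras(dispensations, gap_days = gap_days)
  }
  if (nrow(eras) == 0L) return(FALSE)
  stopifnot(is.data.frame(dispensations))
  idx <- as_day(index_date)
  lo <- idx - lookback_days
  day <- as_day(dispensations$date)
  for (k in seq_len(nrow(eras))) {
    members <- eras$member_dispensations[[k]]
    n_in <- sum(day[members] >= lo & day[members] < idx)
    if (n_in >= min_dispensations &&
        (!require_active || as_day(eras$coverage_end[k]) >= idx))
      return(TRUE)
  }
  FALSE
}

#' @export
print.drug_era_table <- function(x, ...) {
  cat("Drug eras:", nrow(x), "era(s)\n")
  if (nrow(x)) {
    show <- data.frame(start = x$start, coverage_end = x$coverage_end,
                       n_dispensations = x$n_dispensations)
    print(show, ...)
  }
  invisible(x)
}

# Vectorised era scan over a full dispensation table (internal pipeline
# path).  `disp` must have patient_id, drug_class, date, amount_ddd.
# Returns disp augmented with era id (global), cov_start, cov_end (numeric
# days), ordered by patient, class, date.
era_scan_table <- function(disp, gap_days = 60) {
  day <- as_day(disp$date)
  o <- order(disp$patient_id, disp$drug_class, day)
  disp <- disp[o, , drop = FALSE]
  day <- day[o]
  grp <- as.integer(interaction(disp$patient_id, disp$drug_class, drop = TRUE))
  # interaction() does not order by first appearance; re-id by run boundaries
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gid <- cumsum(new_grp)
  scan <- era_scan_cpp(day, as.numeric(disp$amount_ddd), gid, gap_days)
  disp$day <- day
  disp$era <- scan$era
  disp$cov_start <- scan$cov_start
  disp$cov_end <- scan$cov_end
  disp
}
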