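#' Hand-checkable worked fixture of 20 patients
#'
#' A small deterministic claims bundle whose drug eras, PDC values,
#' eligibility decisions, matched sets and conditional-likelihood estimate
#' are all verifiable by hand.  Index date 2017-01-01; the one-year
#' follow-up is 2017.  Construction (all supply in 30-DDD packs unless
#' noted):
#'
#' * **P01** (exposed, M, 70, blood-pressure class): dispensations
#'   2016-01-01, then 2016-04-01/05-01/06-01.  The first pack covers to
#'   2016-01-31; the next dispensation comes 61 days later, so P01 has
#'   exactly two eras, the second with three chained dispensations
#'   (prevalent user).  No follow-up supply: PDC 0.
#' * **P02** (exposed, F, 60): standard pre-index chain (2016-10-03,
#'   11-02, 12-02, coverage ending exactly at the index date) plus one
#'   365-DDD dispensation on 2017-01-01: PDC 1.0, category high.
#' * **P03** (exposed, M, 65, also glucose class): glucose PDC 330/365
#'   (high); clinical controls 2 HbA1c + 1 lipid + 1 creatinine, no
#'   albumin, no eye exam — 3 of 5 satisfied, not high at the 4-of-5 rule,
#'   high at the 3-of-5 sensitivity rule.
#' * **P04** (exposed, F, 80): no age-compatible comparator exists, so the
#'   matcher drops her.
#' * **P05**: mental-health episode closed 2016-06-30 — neither exposed
#'   nor an eligible comparator.
#' * **P06-P17**: comparator pool.  P07 is high (300 days covered); P06 low
#'   with a bridged 30-day hospital stay (100 dispensed + 30 bridged = 130
#'   covered days); the rest low or very low.
#' * **P18** (aged under 18), **P19** (died 2017-07-20, 200 days after
#'   index), **P20** (resident only since 2016-06-01): each fails exactly
#'   one eligibility criterion, so 17 of 20 are retained.
#'
#' Every patient has 12 healthcare contacts in the two pre-index years
#' (dispensations topped up with out-patient visits), so the whole pool
#' shares one contact-volume decile and matching is driven by gender and
#' age alone.  P03 is a prevalent user of both classes, so the
#' blood-pressure matching also forms a 1:2 set around him; nobody in it
#' has any follow-up blood-pressure supply, so that set is
#' outcome-concordant and dropped at fitting.  The blood-pressure analysis
#' then has two informative 1:3 sets —
#' in one only a comparator is the case, in the other only the exposed
#' member — whose exact conditional likelihood `e^b / (e^b + 3)^2` is
#' maximised at odds ratio exactly 3.
#'
#' @return a `claims_bundle` (without generator truth tables).
#' @export
worked_fixture <- function() {
  idx <- as.Date("2017-01-01")
  age <- c(70, 60, 65, 80, 67, 69, 70, 71, 59, 61,
           60, 65, 66, 30, 40, 45, 50, 16, 77, 62)
  gender <- c("M", "F", "M", "F", "M", "M", "M", "M", "F", "F",
              "F", "M", "M", "F", "M", "F", "M", "M", "M", "F")
  id <- sprintf("P%02d", 1:20)
  birth <- as.Date(sprintf("%d-07-01", 2016 - age))   # mid-year birthdays
  patients <- data.frame(
    patient_id = id, gender = gender, birth_date = birth,
    residency_start = as.Date(rep("2000-01-01", 20)),
    death_date = as.Date(rep(NA, 20)),
    emigration_date = as.Date(rep(NA, 20)),
    mcs_score = rep(c(1, 4, 2, 6), 5), stringsAsFactors = FALSE)
  patients$death_date[19] <- as.Date("2017-07-20")       # 200 days post-index
  patients$residency_start[20] <- as.Date("2016-06-01")  # under 2 years

  chain <- function(pid, cls)
    data.frame(patient_id = pid,
               date = as.Date(c("2016-10-03", "2016-11-02", "2016-12-02")),
               drug_class = cls, amount_ddd = 30, stringsAsFactors = FALSE)
  w_disp <- function(pid, cls, amount)
    data.frame(patient_id = pid, date = idx, drug_class = cls,
               amount_ddd = amount, stringsAsFactors = FALSE)
  disp <- do.call(rbind, c(
    list(data.frame(patient_id = "P01",
                    date = as.Date(c("2016-01-01", "2016-04-01",
                                     "2016-05-01", "2016-06-01")),
                    drug_class = "BP", amount_ddd = 30,
                    stringsAsFactors = FALSE)),
    lapply(id[-1], chain, cls = "BP"),
    lapply(c("P03", "P12", "P13"), chain, cls = "GLUCOSE"),
    list(w_disp("P02", "BP", 365),
         w_disp("P07", "BP", 300),
         w_disp("P06", "BP", 100), w_disp("P08", "BP", 100),
         w_disp("P09", "BP", 60), w_disp("P10", "BP", 60),
         w_disp("P11", "BP", 60),
         w_disp("P03", "GLUCOSE", 330),
         w_disp("P12", "GLUCOSE", 30),
         w_disp("P13", "GLUCOSE", 300))))
  # P06: 30-day stay inside the uncovered stretch, regimen observed before
  # admission, so the stay bridges: 100 + 30 covered days
  stays <- data.frame(patient_id = "P06",
                      admission_date = as.Date("2017-05-01"),
                      discharge_date = as.Date("2017-05-31"),
                      diagnosis = "CARDIOVASCULAR", stringsAsFactors = FALSE)
  controls <- data.frame(
    patient_id = c(rep("P03", 4), rep("P12", 6)),
    date = as.Date(c("2017-03-01", "2017-09-01", "2017-04-10", "2017-04-10",
                     "2017-02-01", "2017-08-01", "2017-03-05", "2017-03-05",
                     "2017-05-05", "2017-06-05")),
    service_code = c("HBA1C", "HBA1C", "CHOL_TOT", "CREATININE",
                     "HBA1C", "HBA1C", "CHOL_TOT", "CREATININE",
                     "URINE_ALBUMIN", "EYE_EXAM"),
    stringsAsFactors = FALSE)
  # top every patient up to exactly 12 pre-index contacts
  pre_disp <- table(factor(disp$patient_id[disp$date < idx], levels = id))
  n_visit <- 12L - as.integer(pre_disp)
  visits <- data.frame(
    patient_id = rep(id, n_visit),
    date = idx - unlist(lapply(n_visit, function(k) seq_len(k) * 20L)),
    service_code = "VISIT", stringsAsFactors = FALSE)
  services <- rbind(visits, controls)
  mh <- data.frame(
    patient_id = c("P01", "P02", "P03", "P04", "P05"),
    diagnosis = c("depression", "bipolar disorder", "schizophrenia",
                  "personality disorder", "depression"),
    episode_open = as.Date(c("2010-05-01", "2012-03-01", "2008-01-01",
                             "2015-01-01", "2014-01-01")),
    episode_close = as.Date(c(NA, NA, NA, NA, "2016-06-30")),
    stringsAsFactors = FALSE)
  o <- order(disp$patient_id, disp$drug_class, disp$date)
  disp <- disp[o, , drop = FALSE]; rownames(disp) <- NULL
  bundle <- list(patients = patients, dispensations = disp,
                 hospital_stays = stays, outpatient_services = services,
                 mental_health_records = mh,
                 config = claims_scenario(n_patients = 20, seed = 0L),
                 manifest = list(seed = 0L, config_hash = "worked-fixture",
                                 n_patients = 20L))
  class(bundle) <- "claims_bundle"
  bundle
}
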