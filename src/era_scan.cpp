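#include <Rcpp.h>
using namespace Rcpp;

// Scan one patient-drug dispensation stream (sorted by date) and chain
// dispensations into drug eras with supply stockpiling.
//
// Supply carried over: the effective coverage of dispensation i starts at
// max(date_i, previous coverage end) and lasts amount_i days.  A new era
// begins when date_i exceeds the running coverage end by more than gap
// days (a dispensation exactly `gap` days after coverage end still chains).
//
// `group` must be an integer id that changes between independent streams
// (patient x drug class); within a group dates must be non-decreasing.
//
// Returns per-dispensation vectors: era id (1-based, running across the
// whole input), effective coverage start and end (same day units as date).
// [[Rcpp::export]]
List era_scan_cpp(NumericVector date, NumericVector amount,
                  IntegerVector group, double gap) {
  const R_xlen_t n = date.size();
  if (amount.size() != n || group.size() != n)
    stop("date, amount and group must have equal length");
  IntegerVector era(n);
  NumericVector cov_start(n), cov_end(n);
  int era_id = 0;
  int cur_group = NA_INTEGER;
  double end = R_NegInf;
  double prev_date = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!(amount[i] > 0)) stop("amount_ddd must be positive (row %d)", (int)(i + 1));
    bool new_group = (i == 0) || (group[i] != cur_group);
    if (!new_group && date[i] < prev_date)
      stop("dispensations must be sorted by date within patient-drug (row %d)",
           (int)(i + 1));
    if (new_group || date[i] - end > gap) {
      ++era_id;
      end = date[i];
    }
    double s = std::max(date[i], end);
    cov_start[i] = s;
    cov_end[i] = s + amount[i];
    end = cov_end[i];
    cur_group = group[i];
    prev_date = date[i];
    era[i] = era_id;
  }
  return List::create(_["era"] = era, _["cov_start"] = cov_start,
                      _["cov_end"] = cov_end);
}
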