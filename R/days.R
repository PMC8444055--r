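# Internal calendar helpers.  All date arithmetic is carried out on numeric
# day counts (days since 1970-01-01, i.e. unclass(Date)); user-facing
# functions accept Date or ISO-8601 character and convert on entry.

as_day <- function(x) {
  if (inherits(x, "Date")) return(as.numeric(x))
  if (is.character(x) || is.factor(x)) return(as.numeric(as.Date(as.character(x))))
  as.numeric(x)
}

as_date <- function(day) as.Date(day, origin = "1970-01-01")

# Number of whole calendar days fully contained in the half-open real
# interval [s, e): integer d is counted iff s <= d and d + 1 <= e.
# Fractional supply at either edge is rounded down to whole days.
whole_days <- function(s, e) {
  pmax(0, floor(e - 1) - ceiling(s) + 1)
}

# Merge a set of half-open intervals (numeric starts/ends) into maximal
# disjoint intervals.  Returns a list(start=, end=); empty input allowed.
merge_intervals <- function(start, end) {
  keep <- end > start
  start <- start[keep]; end <- end[keep]
  if (!length(start)) return(list(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  run_end <- cummax(end)
  # a new run begins where an interval starts after the running max end
  new_run <- c(TRUE, start[-1] > run_end[-length(run_end)])
  id <- cumsum(new_run)
  list(start = start[new_run],
       end = as.numeric(tapply(end, id, max)))
}

# Clip intervals to the window [w0, w1).
clip_intervals <- function(iv, w0, w1) {
  s <- pmax(iv$start, w0); e <- pmin(iv$end, w1)
  keep <- e > s
  list(start = s[keep], end = e[keep])
}

# Whole days covered by a union of (already merged) intervals.
covered_day_count <- function(iv) {
  if (!length(iv$start)) return(0L)
  as.integer(sum(whole_days(iv$start, iv$end)))
}

stop_config <- function(...) stop(..., call. = FALSE)
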