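# Independent oracles used across the suite.  These deliberately avoid the
# package's interval arithmetic: eras and coverage are re-derived by walking
# the calendar one day at a time with a supply counter, and the conditional
# likelihood is re-derived by naive enumeration plus a generic optimiser.

# Day-by-day era/coverage simulator for integer-day, integer-amount streams.
# Returns the era id of each dispensation and the set of covered days.
era_oracle <- function(day, amt, gap = 60) {
  n <- length(day)
  stopifnot(n > 0, !is.unsorted(day))
  era <- integer(n)
  supply <- 0
  cov_end <- -Inf     # first uncovered day after the last covered stretch
  cur <- 0L
  covered <- integer(0)
  era_start <- numeric(0)
  era_end <- numeric(0)
  i <- 1L
  t <- day[1]
  while (i <= n || supply > 0) {
    if (i <= n && day[i] == t) {
      while (i <= n && day[i] == t) {
        if (supply == 0 && (cur == 0L || t - cov_end > gap)) {
          if (cur > 0L) era_end[cur] <- cov_end
          cur <- cur + 1L
          era_start[cur] <- t
        }
        supply <- supply + amt[i]
        era[i] <- cur
        i <- i + 1L
      }
    }
    if (supply > 0) {
      covered <- c(covered, t)
      supply <- supply - 1
      cov_end <- t + 1
    }
    t <- if (supply == 0 && i <= n) day[i] else t + 1
  }
  era_end[cur] <- cov_end
  list(era = era, covered = covered, era_start = era_start,
       era_end = era_end)
}

# Boolean-array PDC oracle with hospital bridging (integer amounts/days).
pdc_oracle <- function(disp, window, stays = NULL,
                       bridge = "any_prior_era", spillover = TRUE,
                       gap = 60) {
  w0 <- as.numeric(window$start); w1 <- as.numeric(window$end)
  days <- logical(w1 - w0)
  if (!is.null(disp) && nrow(disp)) {
    d <- as.numeric(as.Date(disp$date))
    o <- order(d)
    orc <- era_oracle(d[o], disp$amount_ddd[o], gap)
    cov <- if (spillover) orc$covered else {
      keep <- d[o] >= w0
      if (any(keep)) era_oracle(d[o][keep], disp$amount_ddd[o][keep],
                                gap)$covered
      else numeric(0)
    }
    cov <- cov[cov >= w0 & cov < w1]
    days[cov - w0 + 1] <- TRUE
    if (!is.null(stays) && nrow(stays) && bridge != "none") {
      adm <- as.numeric(as.Date(stays$admission_date))
      dis <- as.numeric(as.Date(stays$discharge_date))
      for (k in seq_along(adm)) {
        ok <- if (bridge == "any_prior_era") any(d < adm[k]) else
          any(orc$era_start < adm[k] & orc$era_end > adm[k])
        if (!ok) next
        lo <- max(adm[k], w0); hi <- min(dis[k], w1)
        if (hi <= lo) next
        days[seq.int(lo, hi - 1) - w0 + 1] <- TRUE
      }
    }
  }
  sum(days)
}

# Naive conditional log-likelihood by direct per-set enumeration.
naive_cond_loglik <- function(beta, X, y, set_id) {
  ll <- 0
  for (s in unique(set_id)) {
    ix <- which(set_id == s)
    d <- sum(y[ix])
    if (d == 0 || d == length(ix)) next
    eta <- as.vector(X[ix, , drop = FALSE] %*% beta)
    num <- sum(eta[y[ix] == 1])
    combos <- utils::combn(length(ix), d)
    den <- log(sum(exp(colSums(matrix(eta[combos], nrow = d)))))
    ll <- ll + num - den
  }
  ll
}

# Brute-force conditional ML via optim on the naive likelihood.
naive_cond_fit <- function(X, y, set_id) {
  p <- ncol(X)
  optim(rep(0, p), function(b) -naive_cond_loglik(b, X, y, set_id),
        method = "BFGS", control = list(reltol = 1e-14, maxit = 500))$par
}

# Random dispensation stream (integer days/amounts) for property tests.
random_stream <- function(n = NULL, origin = as.Date("2016-01-01")) {
  if (is.null(n)) n <- sample(1:8, 1)
  day <- sort(sample(0:500, n, replace = TRUE))
  data.frame(date = origin + day,
             amount_ddd = sample(c(10, 15, 30, 60, 90), n, replace = TRUE))
}

random_stays <- function(window, n = NULL) {
  if (is.null(n)) n <- sample(0:2, 1)
  if (n == 0) return(NULL)
  adm <- as.Date(as.numeric(window$start) + sample(0:340, n),
                 origin = "1970-01-01")
  data.frame(admission_date = adm, discharge_date = adm + sample(1:30, n,
                                                                 replace = TRUE))
}
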