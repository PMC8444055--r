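#' @export
print.clr <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Exact conditional logistic regression\n")
  if (!is.null(x$call)) {
    cat("Call: "); print(x$call)
  }
  cat(sprintf("%d members in %d sets (%d informative, %d concordant dropped)\n",
              x$n, x$n_sets, x$n_informative, x$n_dropped))
  cat("\nCoefficients (log odds ratios):\n")
  print(format(coef(x), digits = digits), quote = FALSE)
  invisible(x)
}

#' @export
coef.clr <- function(object, ...) object$coefficients

#' @export
vcov.clr <- function(object, ...) object$vcov

#' @export
logLik.clr <- function(object, ...) {
  structure(object$loglik, df = length(coef(object)), class = "logLik")
}

#' @export
confint.clr <- function(object, parm, level = 0.95, ...) {
  b <- coef(object); se <- sqrt(diag(vcov(object)))
  if (missing(parm)) parm <- names(b)
  z <- qnorm(1 - (1 - level) / 2)
  out <- cbind(b[parm] - z * se[parm], b[parm] + z * se[parm])
  dimnames(out) <- list(parm, sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                         1 - (1 - level) / 2)))
  out
}

#' Summary of an exact conditional logistic fit
#'
#' @param object a [clr()] fit.
#' @param conf.level confidence level for Wald intervals (default 0.95).
#' @param ... unused.
#' @return list of class `summary.clr` with a Wald coefficient table and an
#'   odds-ratio table including the `(OR - 1) x 100` percentage-variation
#'   presentation.
#' @export
summary.clr <- function(object, conf.level = 0.95, ...) {
  b <- coef(object); se <- sqrt(diag(vcov(object)))
  z <- b / se
  p <- 2 * pnorm(-abs(z))
  coefmat <- cbind(Estimate = b, `Std. Error` = se, `z value` = z,
                   `Pr(>|z|)` = p)
  ci <- confint(object, level = conf.level)
  ormat <- cbind(OR = exp(b), `CI low` = exp(ci[, 1]), `CI high` = exp(ci[, 2]),
                 `pct var` = (exp(b) - 1) * 100)
  out <- list(call = object$call, coefficients = coefmat, or = ormat,
              conf.level = conf.level, n = object$n, n_sets = object$n_sets,
              n_informative = object$n_informative, loglik = object$loglik,
              null_loglik = object$null_loglik, iter = object$iter,
              converged = object$converged)
  class(out) <- "summary.clr"
  out
}

#' @export
print.summary.clr <- function(x, digits = max(3L, getOption("digits") - 3L),
                              ...) {
  cat("Exact conditional logistic regression\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("%d members, %d informative sets of %d\n\n",
              x$n, x$n_informative, x$n_sets))
  printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
               has.Pvalue = TRUE)
  cat(sprintf("\nOdds ratios with %g%% Wald CI and (OR-1)x100:\n",
              100 * x$conf.level))
  print(round(x$or, digits))
  cat(sprintf("\nLog-likelihood %.3f (null %.3f), %d Newton iteration(s)\n",
              x$loglik, x$null_loglik, x$iter))
  invisible(x)
}

#' @export
predict.clr <- function(object, newdata = NULL, type = c("lp", "risk"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else {
    mm <- model.matrix(delete.response(terms(object$terms)), newdata)
    mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  }
  lp <- as.vector(X %*% coef(object))
  if (type == "lp") lp else exp(lp)
}

#' @export
residuals.clr <- function(object, type = c("response"), ...) {
  # outcome minus the conditional probability of being a case given the
  # set's case total; sums to zero within each informative set
  object$y - object$fitted
}

#' Simulate outcome configurations from a fitted conditional model
#'
#' Draws, for every informative set, a case configuration from the fitted
#' conditional distribution over within-set subsets (the set's case total is
#' kept fixed, as the conditional likelihood prescribes).
#'
#' @param object a [clr()] fit.
#' @param nsim number of simulated outcome vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return data frame with one column per simulation, rows aligned with the
#'   informative-set members of the fit (see `object$set_id`).
#' @export
simulate.clr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  enum <- object$enum
  S <- as.vector(object$SX %*% coef(object))
  M <- tapply(S, enum$subset_set, max)
  w <- exp(S - M[enum$subset_set])
  denom <- rowsum(w, enum$subset_set, reorder = FALSE)
  pr <- as.vector(w / denom[enum$subset_set])
  by_set <- split(seq_along(pr), enum$subset_set)
  out <- matrix(0L, nrow = length(object$y), ncol = nsim)
  for (k in seq_len(nsim)) {
    pick <- vapply(by_set, function(ix)
      ix[sample.int(length(ix), 1L, prob = pr[ix])], integer(1))
    members <- enum$member[enum$subset %in% pick]
    out[members, k] <- 1L
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Forest-style plot of odds ratios from a conditional logistic fit
#'
#' @param x a [clr()] fit.
#' @param conf.level confidence level (default 0.95).
#' @param ... passed to [plot()].
#' @export
plot.clr <- function(x, conf.level = 0.95, ...) {
  b <- coef(x); ci <- confint(x, level = conf.level)
  k <- length(b)
  plot(exp(b), seq_len(k), xlim = range(exp(ci), 1), ylim = c(0.5, k + 0.5),
       log = "x", pch = 16, yaxt = "n", xlab = "Odds ratio (log scale)",
       ylab = "", panel.first = abline(v = 1, lty = 2, col = "grey60"), ...)
  segments(exp(ci[, 1]), seq_len(k), exp(ci[, 2]), seq_len(k))
  axis(2, at = seq_len(k), labels = names(b), las = 1)
  invisible(x)
}

#' Extract a single-term effect estimate from a conditional logistic fit
#'
#' @param fit a [clr()] fit.
#' @param term coefficient name (default: the first coefficient, typically
#'   the exposure indicator).
#' @param conf.level confidence level (default 0.95).
#' @return list of class `effect_estimate`: `term`, `beta`, `se`,
#'   `or_value`, `ci95` (on the OR scale), `pct_variation` (point and CI
#'   mapped by `(x - 1) * 100`), `p_value`, `n_sets_informative`.
#' @export
effect_estimate <- function(fit, term = names(coef(fit))[1],
                            conf.level = 0.95) {
  b <- coef(fit)[[term]]
  se <- sqrt(vcov(fit)[term, term])
  zq <- qnorm(1 - (1 - conf.level) / 2)
  ci <- exp(c(b - zq * se, b + zq * se))
  out <- list(term = term, beta = b, se = se, or_value = exp(b),
              ci95 = ci, pct_variation = (exp(b) - 1) * 100,
              pct_ci = (ci - 1) * 100,
              p_value = 2 * pnorm(-abs(b / se)),
              n_sets_informative = fit$n_informative)
  class(out) <- "effect_estimate"
  out
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f); (OR-1)x100 = %+.1f%% (%+.1f to %+.1f)\n",
              x$term, x$or_value, x$ci95[1], x$ci95[2],
              x$pct_variation, x$pct_ci[1], x$pct_ci[2]))
  invisible(x)
}

#' Percentage-variation presentation of an odds ratio
#'
#' Maps an odds ratio and its confidence interval through
#' `(x - 1) * 100`, the percentage variation in the likelihood of the
#' outcome.  Reduced adherence is declared when the upper CI bound is below
#' zero, increased adherence when the lower bound is above zero.
#'
#' @param or odds ratio, or a [clr()] fit / [effect_estimate()] (then `term`
#'   selects the coefficient).
#' @param ci_low,ci_high CI bounds on the OR scale (ignored when `or` is a
#'   fit).
#' @param term coefficient name when `or` is a fit.
#' @return list with `pct`, `ci` (length 2), and `direction` one of
#'   `"reduced"`, `"increased"`, `"none"`.
#' @examples
#' percent_variation(0.76, 0.74, 0.78)  # -24% (-26 to -22), reduced
#' @export
percent_variation <- function(or, ci_low = NA, ci_high = NA,
                              term = NULL) {
  if (inherits(or, "clr"))
    or <- effect_estimate(or, term = if (is.null(term))
      names(coef(or))[1] else term)
  if (inherits(or, "effect_estimate")) {
    ci_low <- or$ci95[1]; ci_high <- or$ci95[2]; or <- or$or_value
  }
  pct <- (or - 1) * 100
  ci <- (c(ci_low, ci_high) - 1) * 100
  direction <- if (!anyNA(ci) && ci[2] < 0) "reduced"
  else if (!anyNA(ci) && ci[1] > 0) "increased"
  else "none"
  list(pct = pct, ci = ci, direction = direction)
}

#' Stratified conditional logistic estimates
#'
#' Refits the conditional logistic model separately within each stratum of
#' a set-level variable.  Strata must be constant within a matched set; for
#' a member-level variable the label of the set's exposed member (or, if
#' `exposure` is absent, the first member) defines the set's stratum.
#'
#' @param formula,data,set as in [clr()].
#' @param strata_variable name of the stratification column in `data`.
#' @param exposure name of the exposure column used to pick the defining
#'   member when the variable varies within a set (default `"exposed"` when
#'   present).
#' @param term coefficient reported per stratum (default first).
#' @param ... passed to [clr()].
#' @return data frame with one row per stratum: `stratum`, `beta`, `se`,
#'   `or`, `ci_low`, `ci_high`, `pct`, `n_sets`; strata with no informative
#'   sets are absent.  The per-stratum fits are attached as attribute
#'   `"fits"`.
#' @export
stratified_estimates <- function(formula, data, set, strata_variable,
                                 exposure = if ("exposed" %in% names(data))
                                   "exposed" else NULL,
                                 term = NULL, ...) {
  sid <- if (is.character(set) && length(set) == 1L) data[[set]] else set
  lab <- data[[strata_variable]]
  set_lab <- set_level_label(lab, sid,
                             exposed = if (!is.null(exposure))
                               data[[exposure]] else NULL)
  row_lab <- set_lab[match(as.character(sid), names(set_lab))]
  strata <- unique(stats::na.omit(as.character(set_lab)))
  rows <- list(); fits <- list()
  for (st in strata) {
    dsub <- data[!is.na(row_lab) & row_lab == st, , drop = FALSE]
    ssub <- sid[!is.na(row_lab) & row_lab == st]
    fit <- tryCatch(clr(formula, dsub, ssub, quiet = TRUE, ...),
                    error = function(e) NULL)
    if (is.null(fit)) next
    tm <- if (is.null(term)) names(coef(fit))[1] else term
    ee <- effect_estimate(fit, tm)
    rows[[st]] <- data.frame(stratum = st, beta = ee$beta, se = ee$se,
                             or = ee$or_value, ci_low = ee$ci95[1],
                             ci_high = ee$ci95[2], pct = ee$pct_variation,
                             n_sets = fit$n_informative)
    fits[[st]] <- fit
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "fits") <- fits
  out
}

# Set-level label: the common value when constant within set, otherwise the
# exposed member's value.
set_level_label <- function(lab, sid, exposed = NULL) {
  sid <- as.character(sid)
  pick <- function(ix) {
    v <- lab[ix]
    if (length(unique(v)) == 1L) return(as.character(v[1]))
    if (!is.null(exposed) && any(exposed[ix] == 1))
      return(as.character(v[which(exposed[ix] == 1)[1]]))
    as.character(v[1])
  }
  ix_by_set <- split(seq_along(lab), sid)
  vapply(ix_by_set, pick, character(1))
}

#' Inverse-variance homogeneity test across stratum estimates
#'
#' Cochran-style chi-square test of the hypothesis that stratum-specific
#' log odds ratios are equal: `Q = sum w_k (b_k - b_bar)^2` with
#' `w_k = 1/se_k^2` and `b_bar` the inverse-variance weighted mean,
#' referred to a chi-square distribution with `K - 1` degrees of freedom.
#'
#' @param beta stratum log odds ratios (or a data frame from
#'   [stratified_estimates()]).
#' @param se matching standard errors.
#' @return list with `Q`, `df`, `p_value`.
#' @examples
#' homogeneity_test(c(0, 0.5), c(0.1, 0.1))  # Q = 12.5 on 1 df
#' @export
homogeneity_test <- function(beta, se) {
  if (is.data.frame(beta)) { se <- beta$se; beta <- beta$beta }
  if (length(beta) < 2) stop_config("homogeneity test needs >= 2 strata")
  if (any(se <= 0)) stop_config("standard errors must be positive")
  w <- 1 / se^2
  bbar <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bbar)^2)
  df <- length(beta) - 1L
  list(Q = Q, df = df, p_value = pchisq(Q, df, lower.tail = FALSE))
}

#' Trend test across ordered stratum estimates
#'
#' Inverse-variance weighted linear regression of stratum log odds ratios
#' on numeric stratum scores; the Wald test of the slope assesses a
#' monotone trend along the ordered categories.
#'
#' @param beta stratum log odds ratios (or a data frame from
#'   [stratified_estimates()]).
#' @param se matching standard errors.
#' @param scores numeric scores of the ordered strata.
#' @return list with `slope`, `se`, `z`, `p_value`.
#' @export
trend_test <- function(beta, se, scores) {
  if (is.data.frame(beta)) {
    if (missing(scores)) scores <- se
    se <- beta$se; beta <- beta$beta
  }
  if (length(beta) < 2) stop_config("trend test needs >= 2 strata")
  if (length(unique(scores)) < 2) stop_config("scores must not be constant")
  if (any(se <= 0)) stop_config("standard errors must be positive")
  w <- 1 / se^2
  xbar <- sum(w * scores) / sum(w)
  sxx <- sum(w * (scores - xbar)^2)
  slope <- sum(w * (scores - xbar) * beta) / sxx
  slope_se <- sqrt(1 / sxx)
  z <- slope / slope_se
  list(slope = slope, se = slope_se, z = z, p_value = 2 * pnorm(-abs(z)))
}

#' z-test comparing two independent coefficients
#'
#' @param b1,b2 coefficients (log odds ratios).
#' @param se1,se2 their standard errors.
#' @return list with `z` and two-sided `p_value`.
#' @examples
#' compare_coefficients_z(-0.288, 0.05, -0.105, 0.06)  # z approx -2.343
#' @export
compare_coefficients_z <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop_config("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Sensitivity analyses over alternative outcome definitions
#'
#' Refits the conditional logistic model once per outcome column (e.g. high
#' PDC at the 70, 75 and 80% thresholds, high clinical controls at 4-of-5
#' and 3-of-5) and tabulates the effect estimates side by side.
#'
#' @param data matched-set member data.
#' @param set set identifier (column name or vector).
#' @param outcomes character vector of 0/1 outcome columns in `data`.
#' @param rhs right-hand side of the model formula (default `"exposed"`).
#' @param ... passed to [clr()].
#' @return data frame with one row per outcome definition: `outcome`,
#'   `beta`, `se`, `or`, `ci_low`, `ci_high`, `pct`, `pct_low`, `pct_high`,
#'   `n_sets`.  Outcomes whose sets are all concordant yield a row of `NA`.
#' @export
sensitivity_suite <- function(data, set, outcomes, rhs = "exposed", ...) {
  rows <- lapply(outcomes, function(oc) {
    f <- stats::as.formula(paste(oc, "~", rhs))
    fit <- tryCatch(clr(f, data, set, quiet = TRUE, ...),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(outcome = oc, beta = NA_real_, se = NA_real_,
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        pct = NA_real_, pct_low = NA_real_,
                        pct_high = NA_real_, n_sets = 0L))
    ee <- effect_estimate(fit)
    data.frame(outcome = oc, beta = ee$beta, se = ee$se, or = ee$or_value,
               ci_low = ee$ci95[1], ci_high = ee$ci95[2],
               pct = ee$pct_variation, pct_low = ee$pct_ci[1],
               pct_high = ee$pct_ci[2], n_sets = fit$n_informative)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
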