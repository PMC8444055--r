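#' Exact conditional logistic regression for matched sets
#'
#' Fits the conditional logistic model for 1:M matched data by maximising
#' the exact conditional likelihood.  For a matched set \eqn{s} whose
#' \eqn{n_s} members have covariate rows \eqn{x_i} and binary outcomes
#' \eqn{y_i} with case total \eqn{d_s = \sum_i y_i}, the contribution is
#' \deqn{\frac{\exp(\sum_{i: y_i = 1} x_i'\beta)}
#'            {\sum_{C \subseteq s,\ |C| = d_s} \exp(\sum_{i \in C} x_i'\beta)},}
#' the probability of the observed case configuration given the set's case
#' total.  Set-specific intercepts — and any covariate constant within every
#' set, such as the matching variables — are conditioned out.  The
#' denominator is computed by full enumeration of the within-set subsets
#' (matched designs with up to a handful of members per set make this
#' exact and cheap: a 1:3 set has at most 6 subsets); no Breslow or Efron
#' approximation is involved.
#'
#' Maximisation is by Newton–Raphson on the conditional log-likelihood with
#' step-halving when a step decreases it; the observed information (the
#' within-set covariance of subset sums) supplies both the step and the
#' standard errors.  Sets whose outcome is concordant (all cases or all
#' non-cases) carry no information and are dropped with a message.
#' Separation — a covariate whose conditional likelihood increases without
#' bound — is reported as an error naming the offending covariate.
#'
#' @param formula model formula, `outcome ~ exposure + covariates`.  The
#'   outcome must be 0/1 (or logical) for every set member.  No intercept is
#'   fitted (it is conditioned out); an intercept term in the formula is
#'   silently removed.
#' @param data data frame with one row per matched-set member.
#' @param set matched-set identifier: either the name of a column of `data`
#'   or a vector of length `nrow(data)`.
#' @param tol convergence tolerance on the gradient norm (default `1e-8`).
#' @param max_iter maximum Newton iterations (default 100).
#' @param quiet suppress the dropped-set message.
#' @return An object of class `"clr"` with components `coefficients`,
#'   `vcov`, `loglik`, `null_loglik`, `iter`, `converged`, `n`,
#'   `n_sets`, `n_informative`, `fitted` (conditional case probabilities
#'   given each set's case total), and the model frame ingredients needed by
#'   the methods ([summary.clr()], [simulate.clr()], [plot.clr()], plus
#'   `coef`, `vcov`, `confint`, `predict` and `residuals` methods).
#' @examples
#' sets <- simulate_matched_sets(300, true_log_or = log(2), seed = 1)
#' fit <- clr(y ~ exposed, data = sets, set = "set_id")
#' summary(fit)
#' percent_variation(fit)
#' @references Breslow NE, Day NE. Statistical Methods in Cancer Research,
#'   Volume I: The Analysis of Case-Control Studies. IARC, 1980.
#' @export
clr <- function(formula, data, set, tol = 1e-8, max_iter = 100,
                quiet = FALSE) {
  cl <- match.call()
  mf <- model.frame(formula, data, na.action = na.fail)
  y <- model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1))) stop("outcome must be binary (0/1)")
  X <- model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) == 0L) stop("model has no covariates")
  set_id <- if (is.character(set) && length(set) == 1L) {
    if (!set %in% names(data)) stop("set column '", set, "' not found")
    data[[set]]
  } else set
  if (length(set_id) != nrow(X)) stop("set must match rows of data")
  fit <- clr_fit(X, as.numeric(y), set_id, tol = tol, max_iter = max_iter,
                 quiet = quiet)
  fit$call <- cl
  fit$terms <- attr(mf, "terms")
  fit
}

# Engine working on a plain design matrix.  Exported for programmatic use.
#' @rdname clr
#' @param X design matrix (no intercept column).
#' @param y 0/1 outcome vector.
#' @param set_id set identifier vector.
#' @export
clr_fit <- function(X, y, set_id, tol = 1e-8, max_iter = 100, quiet = FALSE) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  sid <- factor(set_id, levels = unique(set_id))
  ord <- order(as.integer(sid))
  X <- X[ord, , drop = FALSE]; y <- y[ord]; sid <- sid[ord]
  n_sets_all <- nlevels(sid)
  d <- tapply(y, sid, sum)
  n_s <- tabulate(sid)
  informative <- d > 0 & d < n_s
  keep <- informative[as.integer(sid)]
  n_dropped <- sum(!informative)
  if (!any(informative)) stop("no informative (outcome-discordant) matched sets")
  if (n_dropped && !quiet)
    message("dropping ", n_dropped, " concordant (uninformative) set(s)")
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  sid <- droplevels(sid[keep])
  n_inf <- nlevels(sid)
  # covariates with no within-set variation are inestimable
  for (j in seq_len(p)) {
    rng <- tapply(X[, j], sid, function(v) max(v) - min(v))
    if (all(rng == 0))
      stop("covariate '", colnames(X)[j],
           "' is constant within every informative set; inestimable")
  }
  enum <- enumerate_subsets(sid, y)
  SX <- rowsum(X[enum$member, , drop = FALSE], enum$subset, reorder = FALSE)
  obs_sum <- colSums(X * y)
  subset_set <- enum$subset_set          # set index of each subset
  obs_subset <- enum$obs_subset          # which subset is the observed one
  beta <- rep(0, p)
  loglik_at <- function(S) {
    # S: subset linear predictor sums
    M <- as.vector(tapply(S, subset_set, max))
    w <- exp(S - M[subset_set])
    denom <- rowsum(w, subset_set, reorder = FALSE)[, 1]
    list(ll = sum(S[obs_subset]) - sum(log(denom) + M),
         w = w, denom = denom)
  }
  S <- as.vector(SX %*% beta)
  cur <- loglik_at(S)
  ll <- cur$ll
  converged <- FALSE
  iter <- 0L
  grad <- NULL; info <- NULL
  repeat {
    pr <- as.vector(cur$w / cur$denom[subset_set])
    ES <- rowsum(SX * pr, subset_set, reorder = FALSE)     # n_inf x p
    grad <- obs_sum - colSums(ES)
    ESS <- crossprod(SX, SX * pr)                          # sum_C p * s s'
    info <- ESS - crossprod(ES)
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    iter <- iter + 1L
    if (iter > max_iter) break
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step)) clr_separation_error(beta, info, colnames(X))
    # step-halving on likelihood decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      S_new <- as.vector(SX %*% beta_new)
      cand <- loglik_at(S_new)
      if (cand$ll >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    beta <- beta_new; cur <- cand; ll <- cand$ll
    if (max(abs(beta)) > 15) clr_separation_error(beta, info, colnames(X))
  }
  if (!converged)
    warning("Newton-Raphson did not reach tolerance in ", max_iter,
            " iterations (gradient norm ", format(sqrt(sum(grad^2))), ")")
  vc <- tryCatch(solve(info), error = function(e)
    clr_separation_error(beta, info, colnames(X)))
  dimnames(vc) <- list(colnames(X), colnames(X))
  # conditional case-membership probabilities per member
  pr <- as.vector(cur$w / cur$denom[subset_set])
  fitted <- numeric(length(y))
  agg <- rowsum(pr[enum$subset], enum$member)
  fitted[as.numeric(rownames(agg))] <- agg[, 1]
  ll0 <- {
    S0 <- numeric(nrow(SX)); loglik_at(S0)$ll
  }
  out <- list(coefficients = setNames(as.vector(beta), colnames(X)),
              vcov = vc, loglik = ll, null_loglik = ll0,
              iter = iter, converged = converged,
              n = length(y), n_sets = n_sets_all, n_informative = n_inf,
              n_dropped = n_dropped,
              fitted = fitted, y = y, X = X, set_id = sid,
              enum = enum, SX = SX)
  class(out) <- "clr"
  out
}

# Enumerate, for every informative set, all case subsets of its observed
# size.  Returns flat index structures:
#   subset       : subset id for each (subset, member) pair
#   member       : row index for each pair
#   member_subset: alias of subset for the member-probability rollup
#   subset_set   : set index (1..n_sets) of each subset
#   obs_subset   : subset id matching the observed cases, one per set
enumerate_subsets <- function(sid, y) {
  idx_by_set <- split(seq_along(y), sid)
  n_sets <- length(idx_by_set)
  combo_cache <- list()
  subset_l <- vector("list", n_sets)
  member_l <- vector("list", n_sets)
  n_subsets_per <- integer(n_sets)
  obs_local <- integer(n_sets)
  for (s in seq_len(n_sets)) {
    rows <- idx_by_set[[s]]
    n <- length(rows); dd <- sum(y[rows])
    key <- paste0(n, ".", dd)
    cmb <- combo_cache[[key]]
    if (is.null(cmb)) {
      cmb <- utils::combn(n, dd)
      combo_cache[[key]] <- cmb
    }
    k <- ncol(cmb)
    n_subsets_per[s] <- k
    subset_l[[s]] <- rep(seq_len(k), each = nrow(cmb))
    member_l[[s]] <- rows[as.vector(cmb)]
    # the subset matching the observed case configuration
    case_local <- which(y[rows] == 1)
    obs_local[s] <- which(colSums(matrix(cmb %in% case_local,
                                         nrow = nrow(cmb))) == dd)[1]
  }
  offset <- c(0L, cumsum(n_subsets_per))[seq_len(n_sets)]
  subset <- unlist(subset_l, use.names = FALSE) +
    rep.int(offset, lengths(subset_l))
  list(subset = subset,
       member = unlist(member_l, use.names = FALSE),
       subset_set = rep.int(seq_len(n_sets), n_subsets_per),
       obs_subset = offset + obs_local,
       n_subsets = sum(n_subsets_per))
}

clr_separation_error <- function(beta, info, nm) {
  worst <- nm[which.max(abs(beta))]
  dv <- diag(as.matrix(info))
  if (any(dv <= 1e-12)) worst <- nm[which.min(dv)]
  stop("conditional likelihood appears unbounded (separation); ",
       "offending covariate: '", worst, "'", call. = FALSE)
}
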