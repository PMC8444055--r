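test_that("1:1 discordant pairs give the closed-form odds ratio", {
  # 12 pairs where only the exposed member is a case, 6 where only the
  # comparator is: conditional ML odds ratio is exactly 12/6 = 2
  d <- data.frame(set_id = rep(1:18, each = 2), exposed = rep(c(1, 0), 18),
                  y = c(rep(c(1, 0), 12), rep(c(0, 1), 6)))
  fit <- clr(y ~ exposed, d, "set_id", quiet = TRUE)
  expect_equal(unname(exp(coef(fit))), 2, tolerance = 1e-7)
  # SE of log OR for discordant pairs is sqrt(1/a + 1/b)
  expect_equal(unname(sqrt(diag(vcov(fit)))), sqrt(1 / 12 + 1 / 6),
               tolerance = 1e-7)
  # concordant pairs are dropped as uninformative
  d2 <- rbind(d, data.frame(set_id = rep(19:20, each = 2),
                            exposed = rep(c(1, 0), 2), y = rep(1, 4)))
  fit2 <- NULL
  expect_message(fit2 <- clr(y ~ exposed, d2, "set_id"), "concordant")
  expect_equal(coef(fit2), coef(fit))
  expect_equal(fit2$n_dropped, 2L)
})

test_that("optimizer matches brute-force enumeration on random sets", {
  set.seed(7)
  for (rep in 1:12) {
    n_sets <- 30
    sizes <- sample(2:5, n_sets, replace = TRUE)
    set_id <- rep(seq_len(n_sets), sizes)
    n <- length(set_id)
    X <- cbind(exposed = rbinom(n, 1, 0.4), z = round(rnorm(n), 2))
    y <- rbinom(n, 1, 0.45)
    # need at least one informative set with variation in both covariates
    ok <- tryCatch(clr_fit(X, y, set_id, quiet = TRUE), error = function(e) NULL)
    if (is.null(ok)) next
    ref <- naive_cond_fit(ok$X, ok$y, as.integer(ok$set_id))
    expect_equal(unname(coef(ok)), ref, tolerance = 1e-6)
    # and the naive likelihood at the optimum is not beaten nearby
    ll_hat <- naive_cond_loglik(coef(ok), ok$X, ok$y, as.integer(ok$set_id))
    for (k in 1:5) {
      pert <- coef(ok) + rnorm(2, 0, 0.05)
      expect_lte(naive_cond_loglik(pert, ok$X, ok$y, as.integer(ok$set_id)),
                 ll_hat + 1e-9)
    }
  }
})

test_that("agreement with survival::clogit exact likelihood", {
  skip_if_not_installed("survival")
  sm <- simulate_matched_sets(300, true_log_or = log(0.7), seed = 15)
  sm$z <- rnorm(nrow(sm))
  fit <- clr(y ~ exposed + z, sm, "set_id", quiet = TRUE)
  ref <- survival::coxph(
    survival::Surv(rep(1, nrow(sm)), y) ~ exposed + z +
      survival::strata(set_id),
    data = sm, method = "exact")
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(diag(vcov(fit))), unname(diag(vcov(ref))),
               tolerance = 1e-6)
})

test_that("set-constant covariates are conditioned out or rejected", {
  sm <- simulate_matched_sets(200, true_log_or = log(1.5), seed = 21)
  fit0 <- clr(y ~ exposed, sm, "set_id", quiet = TRUE)
  # a covariate constant within each set leaves the exposure beta unchanged
  sm$setvar <- ave(rnorm(nrow(sm)), sm$set_id)  # identical within set
  expect_error(clr(y ~ exposed + setvar, sm, "set_id", quiet = TRUE),
               "constant within every informative set")
  # adding a set-constant to the linear predictor does not move the optimum:
  # refit after centring exposure + noise free check via likelihood identity
  ll_shift <- naive_cond_loglik(coef(fit0), as.matrix(sm$exposed), sm$y,
                                sm$set_id)
  X2 <- cbind(sm$exposed, sm$setvar)
  ll_with <- naive_cond_loglik(c(coef(fit0), 123), X2, sm$y, sm$set_id)
  expect_equal(ll_with, ll_shift, tolerance = 1e-10)
})

test_that("degenerate inputs raise informative errors", {
  # exposure constant within every set: inestimable
  d <- data.frame(set_id = rep(1:5, each = 2), exposed = 1,
                  y = rep(c(1, 0), 5))
  expect_error(clr(y ~ exposed, d, "set_id", quiet = TRUE),
               "constant within every informative set")
  # all sets concordant
  d2 <- data.frame(set_id = rep(1:4, each = 2), exposed = rep(c(1, 0), 4),
                   y = 1)
  expect_error(clr(y ~ exposed, d2, "set_id", quiet = TRUE), "informative")
  # separation: exposed member is the case in every set
  d3 <- data.frame(set_id = rep(1:25, each = 2), exposed = rep(c(1, 0), 25),
                   y = rep(c(1, 0), 25))
  expect_error(clr(y ~ exposed, d3, "set_id", quiet = TRUE),
               "separation.*exposed")
})

test_that("fitted probabilities and residuals respect the set case totals", {
  sm <- simulate_matched_sets(150, true_log_or = log(2), seed = 31)
  fit <- clr(y ~ exposed, sm, "set_id", quiet = TRUE)
  res_by_set <- tapply(residuals(fit), fit$set_id, sum)
  expect_true(all(abs(res_by_set) < 1e-8))
  sims <- simulate(fit, nsim = 5, seed = 99)
  d_obs <- tapply(fit$y, fit$set_id, sum)
  for (k in 1:5)
    expect_equal(unname(tapply(sims[[k]], fit$set_id, sum)), unname(d_obs))
})

test_that("percentage variation transforms point and interval", {
  pv <- percent_variation(0.76, 0.74, 0.78)
  expect_equal(pv$pct, -24)
  expect_equal(pv$ci, c(-26, -22))
  expect_equal(pv$direction, "reduced")
  expect_equal(percent_variation(1, 0.99, 1.03)$direction, "none")
  expect_equal(percent_variation(1.2, 1.1, 1.3)$direction, "increased")
  sm <- simulate_matched_sets(200, true_log_or = 0.4, seed = 41)
  fit <- clr(y ~ exposed, sm, "set_id", quiet = TRUE)
  pv2 <- percent_variation(fit)
  ee <- effect_estimate(fit)
  expect_equal(pv2$pct, (ee$or_value - 1) * 100)
  expect_equal(ee$pct_variation, (exp(ee$beta) - 1) * 100)
})

test_that("homogeneity, trend and z tests match hand calculations", {
  h <- homogeneity_test(c(0, 0.5), c(0.1, 0.1))
  expect_equal(h$Q, 12.5)
  expect_equal(h$df, 1L)
  expect_equal(h$p_value, pchisq(12.5, 1, lower.tail = FALSE))
  expect_equal(homogeneity_test(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))$Q, 0)
  expect_equal(homogeneity_test(c(0.3, 0.3), c(0.1, 0.2))$p_value, 1)
  expect_error(homogeneity_test(0.3, 0.1), ">= 2")

  # betas exactly linear in score are recovered to numerical precision
  sc <- c(1, 2, 3, 4)
  tr <- trend_test(0.1 + 0.25 * sc, rep(0.05, 4), sc)
  expect_equal(tr$slope, 0.25, tolerance = 1e-12)
  expect_equal(trend_test(rep(0.4, 3), c(0.1, 0.1, 0.1), 1:3)$slope, 0)
  expect_error(trend_test(c(0.1, 0.2), c(0.1, 0.1), c(2, 2)), "constant")
  # score-based: permuting stratum order with their scores changes nothing
  o <- c(3, 1, 4, 2)
  tr2 <- trend_test((0.1 + 0.25 * sc)[o], rep(0.05, 4), sc[o])
  expect_equal(tr2$slope, tr$slope)

  z <- compare_coefficients_z(-0.288, 0.05, -0.105, 0.06)
  expect_equal(z$z, (-0.288 + 0.105) / sqrt(0.05^2 + 0.06^2))
  expect_equal(z$z, -2.3431, tolerance = 1e-4)
  zs <- compare_coefficients_z(-0.105, 0.06, -0.288, 0.05)
  expect_equal(zs$z, -z$z)
  expect_equal(compare_coefficients_z(0.2, 0.1, 0.2, 0.2)$z, 0)
  expect_equal(compare_coefficients_z(0.2, 0.1, 0.2, 0.2)$p_value, 1)
  expect_error(compare_coefficients_z(0.1, 0, 0.2, 0.1), "positive")
})

test_that("stratified estimates: degenerate single stratum equals pooled fit", {
  sm <- simulate_matched_sets(250, true_log_or = log(0.7), seed = 51)
  sm$grp <- "all"
  est <- stratified_estimates(y ~ exposed, sm, "set_id", "grp")
  fit <- clr(y ~ exposed, sm, "set_id", quiet = TRUE)
  expect_equal(nrow(est), 1L)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  # two identical strata give identical estimates
  sm2 <- sm; sm2$set_id <- sm$set_id + max(sm$set_id); sm2$grp <- "b"
  both <- rbind(sm, sm2)
  est2 <- stratified_estimates(y ~ exposed, both, "set_id", "grp")
  expect_equal(est2$beta[1], est2$beta[2], tolerance = 1e-10)
})

test_that("stratum-specific planted effects are recovered", {
  a <- simulate_matched_sets(2500, true_log_or = log(0.6), seed = 61)
  b <- simulate_matched_sets(2500, true_log_or = log(1.4), seed = 62)
  b$set_id <- b$set_id + max(a$set_id)
  a$grp <- "A"; b$grp <- "B"
  est <- stratified_estimates(y ~ exposed, rbind(a, b), "set_id", "grp")
  est <- est[order(est$stratum), ]
  expect_lt(abs(est$beta[1] - log(0.6)), 3 * est$se[1])
  expect_lt(abs(est$beta[2] - log(1.4)), 3 * est$se[2])
  h <- homogeneity_test(est)
  expect_lt(h$p_value, 0.01)
})

test_that("sensitivity suite reproduces the main analysis in its 75% column", {
  set.seed(71)
  n_sets <- 400
  u <- rnorm(n_sets, 0, 0.5)
  sid <- rep(seq_len(n_sets), each = 4)
  expo <- rep(c(1, 0, 0, 0), n_sets)
  pdc <- plogis(u[sid] - 0.3 * expo + rnorm(length(sid), 0, 1))
  d <- data.frame(set_id = sid, exposed = expo,
                  high_at_70 = as.integer(pdc >= 0.55),
                  high_at_75 = as.integer(pdc >= 0.6),
                  high_at_80 = as.integer(pdc >= 0.65))
  tab <- sensitivity_suite(d, "set_id",
                           c("high_at_70", "high_at_75", "high_at_80"))
  main <- clr(high_at_75 ~ exposed, d, "set_id", quiet = TRUE)
  expect_equal(tab$beta[tab$outcome == "high_at_75"], unname(coef(main)),
               tolerance = 1e-10)
  expect_equal(nrow(tab), 3L)
  # concordant-everywhere outcome yields an NA row, not an error
  d$always <- 1L
  tab2 <- sensitivity_suite(d, "set_id", c("high_at_75", "always"))
  expect_true(is.na(tab2$or[tab2$outcome == "always"]))
})

test_that("homogeneity statistic is chi-square distributed under the null", {
  set.seed(81)
  K <- 3; nrep <- 300
  qs <- replicate(nrep, {
    b <- rnorm(K, 0.2, 0.1)   # common true beta 0.2, se 0.1
    homogeneity_test(b, rep(0.1, K))$Q
  })
  # compare empirical quantiles with chi-square(K-1)
  expect_lt(abs(mean(qs > qchisq(0.95, K - 1)) - 0.05), 0.035)
  expect_lt(abs(mean(qs) - (K - 1)), 0.35)
})
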