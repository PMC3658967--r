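test_that("unclustered data drive the variance to zero and match the GLM", {
  set.seed(30)
  fx <- make_clustered_fixture(12, 100, sigma2 = 0, seed = 30)
  re <- fit_random_intercept_logistic(fx$X, fx$y, fx$cluster)
  sf <- fit_standard_logistic(fx$X, fx$y)
  expect_lt(re$sigma2_u0, 1e-3)
  expect_true(re$boundary)
  expect_equal(re$alpha, sf$alpha, tolerance = 1e-3)
  expect_equal(unname(re$beta), unname(sf$beta), tolerance = 1e-3)
  # marginal likelihood degenerates to the ordinary likelihood at sigma2 = 0
  expect_equal(
    glmm_marginal_loglik(sf$alpha, sf$beta, 0, fx$X, fx$y, fx$cluster),
    sf$loglik, tolerance = 1e-8)
})

test_that("variance and coefficients are recovered at ICC 15%", {
  sig2 <- variance_from_icc(0.15)
  ests <- t(vapply(1:20, function(r) {
    fx <- make_clustered_fixture(50, 200, sigma2 = sig2, alpha = -2.1,
                                 beta = c(1, 1), seed = 300 + r)
    f <- fit_random_intercept_logistic(fx$X, fx$y, fx$cluster)
    c(f$sigma2_u0, f$beta)
  }, numeric(3)))
  se_mean <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - sig2), 3 * se_mean[1])
  expect_lt(abs(mean(ests[, 2]) - 1), 3 * se_mean[2])
  expect_lt(abs(mean(ests[, 3]) - 1), 3 * se_mean[3])
})

test_that("adaptive quadrature agrees with a dense non-adaptive quadrature", {
  fx <- make_clustered_fixture(24, 40, sigma2 = variance_from_icc(0.15),
                               seed = 31)
  f <- fit_random_intercept_logistic(fx$X, fx$y, fx$cluster)
  ll101 <- glmm_marginal_loglik(f$alpha, f$beta, f$sigma2_u0,
                                fx$X, fx$y, fx$cluster, nodes = 101)
  expect_lt(abs(ll101 - f$loglik) / abs(f$loglik), 1e-5)
  # the dense quadrature itself is node-stable
  ll201 <- glmm_marginal_loglik(f$alpha, f$beta, f$sigma2_u0,
                                fx$X, fx$y, fx$cluster, nodes = 201)
  expect_equal(ll101, ll201, tolerance = 1e-9)
  # and the fitted node count is converged: refitting with more nodes moves
  # the variance estimate by less than 1e-4
  f25 <- fit_random_intercept_logistic(fx$X, fx$y, fx$cluster, nAGQ = 25)
  expect_lt(abs(f25$sigma2_u0 - f$sigma2_u0), 1e-4)
})

test_that("empirical-Bayes effects shrink toward zero and track the truth", {
  # intercept-only clusters with spread incidences: every u0_hat must be
  # closer to zero than the raw cluster deviation
  set.seed(32)
  n_cl <- 15
  u <- rnorm(n_cl, 0, 1)
  cl <- rep(seq_len(n_cl), each = 60)
  y <- as.integer(runif(length(cl)) <= plogis(-0.8 + u[cl]))
  f <- fit_random_intercept_logistic(NULL, y, cl)
  # unpooled per-cluster MLE deviation (infinite for all-event clusters is fine)
  raw_dev <- qlogis(tapply(y, cl, mean)) - f$alpha
  expect_true(all(abs(f$u0_hat) <= abs(raw_dev) + 1e-6))
  expect_true(all(sign(f$u0_hat) == sign(raw_dev)))
  # large clusters: u0_hat approaches the true u0
  fx_big <- make_clustered_fixture(6, 3000, sigma2 = 1, seed = 33)
  fb <- fit_random_intercept_logistic(fx_big$X, fx_big$y, fx_big$cluster)
  expect_lt(max(abs(fb$u0_hat - fx_big$u)), 0.3)
  # posterior means agree closely with modes on a well-behaved fixture
  pm <- eb_u0(f, type = "mean")
  expect_lt(max(abs(unname(pm) - unname(f$u0_hat))), 0.03)
})

test_that("Wald interval for the variance is finite and covers the estimate", {
  fx <- make_clustered_fixture(40, 100, sigma2 = 0.5, seed = 34)
  f <- fit_random_intercept_logistic(fx$X, fx$y, fx$cluster)
  ci <- ranint_variance_ci(f)
  expect_true(is.finite(ci$se_log_sigma2) && ci$se_log_sigma2 > 0)
  expect_lt(ci$lower, f$sigma2_u0)
  expect_gt(ci$upper, f$sigma2_u0)
})

test_that("mixed calibration-in-the-large recovers an offset shift", {
  fx <- make_clustered_fixture(20, 80, sigma2 = 0.3, alpha = -1, seed = 35)
  f <- fit_random_intercept_logistic(fx$X, fx$y, fx$cluster)
  lp_cond <- predict_conditional(f, fx$X, fx$cluster)$lp
  cal <- fit_mixed_calibration_large(lp_cond - 0.7, fx$y, fx$cluster)
  expect_equal(unname(cal$fixed["intercept"]), 0.7, tolerance = 0.05)
  # single cluster degenerates to the plain offset-model intercept
  one <- fit_mixed_calibration_large(fx$lp[fx$cluster == 1],
                                     fx$y[fx$cluster == 1],
                                     rep(1, sum(fx$cluster == 1)))
  expect_equal(unname(one$re_sd["intercept"]), 0)
  expect_equal(unname(one$fixed["intercept"]),
               calibration_in_the_large(fx$lp[fx$cluster == 1],
                                        fx$y[fx$cluster == 1]),
               tolerance = 1e-6)
})

test_that("mixed calibration slope transforms exactly under lp rescaling", {
  fx <- make_clustered_fixture(20, 80, sigma2 = 0.3, seed = 36)
  s1 <- fit_mixed_calibration_slope(fx$lp, fx$y, fx$cluster)
  s2 <- fit_mixed_calibration_slope(fx$lp / 2, fx$y, fx$cluster)
  expect_equal(unname(s2$fixed["slope"]), 2 * unname(s1$fixed["slope"]),
               tolerance = 5e-3)
  expect_equal(unname(s2$re_sd["slope"]), 2 * unname(s1$re_sd["slope"]),
               tolerance = 0.02)
  # single-cluster self-calibration: a model scored on its own training data
  i <- fx$cluster <= 4
  sf <- fit_standard_logistic(fx$X[i, ], fx$y[i])
  lp_hat <- predict_standard(sf, fx$X[i, ])$lp
  self <- fit_mixed_calibration_slope(lp_hat, fx$y[i], rep(1, sum(i)))
  expect_equal(unname(self$fixed["slope"]), 1, tolerance = 1e-6)
})
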