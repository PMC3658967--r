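test_that("center sizes follow the Poisson-lognormal mixture", {
  set.seed(1)
  # degenerate mixing distribution: plain Poisson(10)
  sizes <- generate_center_sizes(1e4, log_mean = log(10), log_sd = 0)
  expect_true(all(sizes >= 1))
  expect_equal(mean(sizes), 10, tolerance = 0.02)
  # default parameters: median across draws near exp(5.7) = 299
  meds <- replicate(20, median(generate_center_sizes(100)))
  expect_equal(mean(meds), exp(5.7), tolerance = 0.05)
  # total patients near 100 * exp(5.7 + 0.3^2/2) = 31,260
  totals <- replicate(20, sum(generate_center_sizes(100)))
  expect_equal(mean(totals), 100 * exp(5.7 + 0.09 / 2), tolerance = 0.03)
})

test_that("predictors have the stated scales and incidences", {
  set.seed(2)
  X <- generate_predictors(2e4)
  expect_equal(unname(apply(X[, 1:3], 2, sd)), c(0.2, 0.4, 1), tolerance = 0.03)
  expect_equal(unname(colMeans(X[, 4:6])), c(0.2, 0.3, 0.4), tolerance = 0.02)
  expect_true(all(X[, 4:6] %in% 0:1))
})

test_that("x1 can be correlated with the center effect without changing its scale", {
  set.seed(3)
  n_centers <- 200
  sigma_u0 <- sqrt(variance_from_icc(0.05))
  u0 <- rnorm(n_centers, 0, sigma_u0)
  cl <- rep(seq_len(n_centers), each = 50)
  X0 <- generate_predictors(length(cl), cl, u0, corr_x1_u0 = 0)
  expect_lt(abs(cor(X0[, 1], u0[cl])), 0.03)
  X4 <- generate_predictors(length(cl), cl, u0, corr_x1_u0 = 0.4,
                            sigma_u0 = sigma_u0)
  expect_equal(cor(X4[, 1], u0[cl]), 0.4, tolerance = 0.05)
  expect_equal(sd(X4[, 1]), 0.2, tolerance = 0.02)
  expect_error(generate_predictors(10, cl, u0, corr_x1_u0 = 1), "corr")
})

test_that("solve_intercept hits the target incidence (Monte-Carlo check)", {
  # frozen values from a 2e6-draw Monte-Carlo root-finding oracle
  a30 <- solve_intercept(0.30, icc = 0.05)
  a03 <- solve_intercept(0.03, icc = 0.05)
  expect_equal(a30, -2.0495, tolerance = 0.005)
  expect_equal(a03, -5.2611, tolerance = 0.005)
  set.seed(4)
  n <- 2e5
  S <- rnorm(n, 0, sqrt(1.2 + variance_from_icc(0.05))) +
    rbinom(n, 1, 0.2) + rbinom(n, 1, 0.3) + rbinom(n, 1, 0.4)
  expect_lt(abs(mean(plogis(a30 + S)) - 0.30), 0.005)
  expect_lt(abs(mean(plogis(a03 + S)) - 0.03), 0.002)
  expect_error(solve_intercept(0, icc = 0.05))
})

test_that("outcome generation follows the true risks", {
  expect_equal(generate_outcomes(rep(1, 50)), rep(1L, 50))
  expect_equal(generate_outcomes(rep(0, 50)), rep(0L, 50))
  set.seed(5)
  expect_lt(abs(mean(generate_outcomes(rep(0.3, 1e5))) - 0.3), 0.005)
  expect_error(generate_outcomes(c(0.2, 1.2)), "0, 1")
})

test_that("source populations satisfy the linear-predictor and risk identities", {
  cfg <- scenario_config(icc = 0.05, base_seed = 10)
  pop <- generate_source_population(cfg, seed = 10)
  X <- as.matrix(pop[, paste0("x", 1:6)])
  alpha <- attr(pop, "alpha_true")
  expect_equal(pop$lp, alpha + rowSums(X) + pop$u0, tolerance = 1e-12)
  expect_equal(pop$p_true, plogis(pop$lp), tolerance = 1e-12)
  # one u0 value per center, centered near 0 with the target variance
  u_by_center <- tapply(pop$u0, pop$center_id, unique)
  expect_true(all(lengths(u_by_center) == 1))
  u <- unlist(u_by_center)
  expect_lt(abs(mean(u)), 3 * sqrt(0.17 / 100))
  expect_lt(abs(var(u) - variance_from_icc(0.05)), 0.08)
  # variance composition of lp: predictors + random intercept
  v_expect <- 0.04 + 0.16 + 1 + 0.2 * 0.8 + 0.3 * 0.7 + 0.4 * 0.6 +
    variance_from_icc(0.05)
  expect_lt(abs(var(pop$lp) - v_expect), 0.1)
  expect_lt(abs(mean(pop$y) - 0.30), 0.03)
})

test_that("an ICC-0 population has no cluster structure", {
  cfg <- scenario_config(icc = 0, base_seed = 11)
  pop <- generate_source_population(cfg, seed = 11)
  expect_true(all(pop$u0 == 0))
  expect_equal(var(pop$lp), 1.81, tolerance = 0.05)
})

test_that("generation is deterministic given config and seed", {
  cfg <- scenario_config(icc = 0.15, base_seed = 12)
  p1 <- generate_source_population(cfg, seed = 99)
  p2 <- generate_source_population(cfg, seed = 99)
  expect_identical(p1, p2)
})

test_that("two-stage sampling draws centers then pooled patients", {
  cfg <- scenario_config(n_source_centers = 30, center_size_log_mean = 4,
                         center_size_log_sd = 0.2, n_sample_centers = 10,
                         n_sample_patients = 300)
  pop <- generate_source_population(cfg, seed = 13)
  # degenerate: sampling everything returns the population
  all_of_it <- two_stage_sample(pop, 30, nrow(pop))
  expect_equal(all_of_it[, names(pop)], pop, ignore_attr = TRUE)
  set.seed(14)
  s <- two_stage_sample(pop, 10, 300)
  expect_equal(nrow(s), 300)
  expect_lte(length(unique(s$center_id)), 10)
  # sampled rows are genuine population rows with their cluster attributes
  expect_equal(s$u0, pop$u0[s$.source_row])
  expect_error(two_stage_sample(pop, 50, 10), "exceeds the number of centers")
  expect_error(two_stage_sample(pop, 2, nrow(pop)), "exceeds the")
})
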