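# Data-generating process for clustered binary outcomes: 100-center source
# populations with Poisson center sizes mixed over a lognormal, six predictors
# (three continuous, three binary), a normal center random intercept whose
# variance is set by a target latent-scale ICC, and two-stage study sampling.

# Fixed predictor distribution: sds of the three continuous predictors,
# incidences of the three binary predictors; all true coefficients are 1.
PREDICTOR_SD <- c(0.2, 0.4, 1)
PREDICTOR_INCIDENCE <- c(0.2, 0.3, 0.4)
BETA_TRUE <- rep(1, 6)

#' Simulation scenario configuration
#'
#' Bundles every parameter of one simulation scenario: clustering strength
#' (ICC), optional correlation between the first continuous predictor and the
#' center effect, source-population and study-sample dimensions, target outcome
#' incidence, replication count, and base seed.
#'
#' @param icc target intraclass correlation on the latent logistic scale,
#'   in `(0, 1)` (0 allowed: no clustering). The paper-style scenarios use
#'   0.05, 0.15 and 0.30.
#' @param corr_x1_u0 Pearson correlation between predictor x1 and the center
#'   random intercept, in `[0, 1)`. 0 or 0.4 in the scenario grid.
#' @param n_source_centers number of centers in the source population.
#' @param center_size_log_mean,center_size_log_sd parameters of the normal
#'   whose exponential gives each center's Poisson mean size.
#' @param n_sample_centers,n_sample_patients two-stage sample dimensions:
#'   centers drawn first, then patients pooled across the drawn centers.
#' @param target_incidence marginal outcome incidence the fixed intercept is
#'   solved for (0.30, or 0.03 in the low-event scenario).
#' @param n_reps number of Monte-Carlo replications.
#' @param base_seed integer; replication r uses seed `base_seed + r`.
#' @return An object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(icc = 0.05,
                            corr_x1_u0 = 0,
                            n_source_centers = 100,
                            center_size_log_mean = 5.7,
                            center_size_log_sd = 0.3,
                            n_sample_centers = 20,
                            n_sample_patients = 1000,
                            target_incidence = 0.30,
                            n_reps = 100,
                            base_seed = 1L) {
  stopifnot(
    is.numeric(icc), length(icc) == 1, icc >= 0, icc < 1,
    is.numeric(corr_x1_u0), length(corr_x1_u0) == 1,
    corr_x1_u0 >= 0, corr_x1_u0 < 1,
    n_source_centers >= 1, center_size_log_sd >= 0,
    n_sample_centers >= 1, n_sample_centers <= n_source_centers,
    n_sample_patients >= 1,
    target_incidence > 0, target_incidence < 1,
    n_reps >= 1
  )
  if (corr_x1_u0 > 0 && icc == 0) {
    stop("corr_x1_u0 > 0 requires a non-degenerate random intercept (icc > 0)",
         call. = FALSE)
  }
  structure(
    list(
      icc = icc,
      corr_x1_u0 = corr_x1_u0,
      sigma2_u0 = variance_from_icc(icc),
      n_source_centers = as.integer(n_source_centers),
      center_size_log_mean = center_size_log_mean,
      center_size_log_sd = center_size_log_sd,
      n_sample_centers = as.integer(n_sample_centers),
      n_sample_patients = as.integer(n_sample_patients),
      target_incidence = target_incidence,
      n_reps = as.integer(n_reps),
      base_seed = as.integer(base_seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Simulation scenario\n")
  cat(sprintf("  ICC %.3g (sigma2_u0 = %.4f), corr(x1, u0) = %.2g\n",
              x$icc, x$sigma2_u0, x$corr_x1_u0))
  cat(sprintf("  source: %d centers, sizes ~ Poisson(exp(N(%.2f, %.2f^2)))\n",
              x$n_source_centers, x$center_size_log_mean, x$center_size_log_sd))
  cat(sprintf("  sample: %d centers / %d patients; incidence %.2g; %d reps, base seed %d\n",
              x$n_sample_centers, x$n_sample_patients, x$target_incidence,
              x$n_reps, x$base_seed))
  invisible(x)
}

#' Draw center sizes: Poisson counts mixed over a lognormal mean
#'
#' Each center's size is Poisson with mean `exp(z)`, `z ~ N(log_mean,
#' log_sd^2)` independently per center. Centers that draw a size of zero are
#' redrawn so every center has at least one patient.
#'
#' @param n_centers number of centers.
#' @param log_mean,log_sd normal parameters on the log scale (defaults 5.7,
#'   0.3 give a median center size of about exp(5.7) = 299).
#' @return Integer vector of center sizes, all >= 1.
#' @export
generate_center_sizes <- function(n_centers, log_mean = 5.7, log_sd = 0.3) {
  stopifnot(n_centers >= 1, log_sd >= 0)
  sizes <- stats::rpois(n_centers, exp(stats::rnorm(n_centers, log_mean, log_sd)))
  while (any(sizes == 0)) {
    zero <- sizes == 0
    sizes[zero] <- stats::rpois(sum(zero),
                                exp(stats::rnorm(sum(zero), log_mean, log_sd)))
  }
  as.integer(sizes)
}

#' Draw the six predictors, optionally correlating x1 with the center effect
#'
#' Columns 1-3 are continuous N(0, sd) with sds 0.2, 0.4, 1; columns 4-6 are
#' Bernoulli with incidences 0.2, 0.3, 0.4. When `corr_x1_u0 = rho > 0`, x1 is
#' built as `rho * (sd_x1 / sigma_u0) * u0[center] + sqrt(1 - rho^2) * sd_x1 * z`
#' so both `corr(x1, u0) = rho` and `sd(x1) = 0.2` hold.
#'
#' @param n_patients number of rows.
#' @param center_id integer center index per patient (used only when
#'   `corr_x1_u0 > 0`).
#' @param u0 center random intercepts, one per center.
#' @param corr_x1_u0 target Pearson correlation in `[0, 1)`.
#' @param sigma_u0 theoretical sd of the random intercept; required when
#'   `corr_x1_u0 > 0` so that the marginal sd of x1 stays exactly 0.2.
#' @return Numeric matrix `n_patients` x 6 with columns `x1` .. `x6`.
#' @export
generate_predictors <- function(n_patients, center_id = NULL, u0 = NULL,
                                corr_x1_u0 = 0, sigma_u0 = NULL) {
  if (abs(corr_x1_u0) >= 1) stop("|corr_x1_u0| must be < 1", call. = FALSE)
  X <- matrix(0, n_patients, 6, dimnames = list(NULL, paste0("x", 1:6)))
  if (corr_x1_u0 > 0) {
    if (is.null(u0) || is.null(center_id)) {
      stop("u0 and center_id are required when corr_x1_u0 > 0", call. = FALSE)
    }
    if (is.null(sigma_u0)) sigma_u0 <- stats::sd(u0)
    if (sigma_u0 <= 0) {
      stop("u0 has zero variance; cannot correlate x1 with it", call. = FALSE)
    }
    X[, 1] <- corr_x1_u0 * (PREDICTOR_SD[1] / sigma_u0) * u0[center_id] +
      sqrt(1 - corr_x1_u0^2) * PREDICTOR_SD[1] * stats::rnorm(n_patients)
  } else {
    X[, 1] <- stats::rnorm(n_patients, 0, PREDICTOR_SD[1])
  }
  X[, 2] <- stats::rnorm(n_patients, 0, PREDICTOR_SD[2])
  X[, 3] <- stats::rnorm(n_patients, 0, PREDICTOR_SD[3])
  for (k in 1:3) {
    X[, 3 + k] <- stats::rbinom(n_patients, 1, PREDICTOR_INCIDENCE[k])
  }
  X
}

#' Solve the fixed intercept for a target marginal incidence
#'
#' Finds `alpha` with `E[plogis(alpha + sum(x_m) + u0)] = target_incidence`.
#' The continuous predictors and the random intercept are jointly normal, so
#' the expectation reduces to an 8-cell sum over the binary predictors times a
#' 1-D Gauss-Hermite quadrature over the normal part (variance
#' `sum(sd^2) + sigma2_u0 + 2 rho sd_x1 sigma_u0`); the root is then found
#' with `uniroot`. Deterministic (no Monte Carlo).
#'
#' @param target_incidence desired marginal incidence in `(0, 1)`.
#' @param icc latent-scale ICC setting the random-intercept variance.
#' @param corr_x1_u0 correlation between x1 and u0 (adds covariance to the
#'   normal part of the linear predictor).
#' @param nodes number of Gauss-Hermite nodes.
#' @return The fixed intercept `alpha_true` (log-odds).
#' @export
solve_intercept <- function(target_incidence, icc, corr_x1_u0 = 0, nodes = 60) {
  stopifnot(target_incidence > 0, target_incidence < 1)
  sigma2 <- variance_from_icc(icc)
  v <- sum(PREDICTOR_SD^2) + sigma2 +
    2 * corr_x1_u0 * PREDICTOR_SD[1] * sqrt(sigma2)
  gh <- pracma::gaussHermite(nodes)
  # binary cells: values and probabilities of x4 + x5 + x6
  cells <- expand.grid(x4 = 0:1, x5 = 0:1, x6 = 0:1)
  cell_sum <- rowSums(cells)
  cell_pr <- apply(cells, 1, function(r) {
    prod(ifelse(r == 1, PREDICTOR_INCIDENCE, 1 - PREDICTOR_INCIDENCE))
  })
  mean_response <- function(alpha) {
    z <- sqrt(2 * v) * gh$x                       # normal part draws
    m <- outer(cell_sum, z, function(b, zz) stats::plogis(alpha + b + zz))
    sum(cell_pr * (m %*% gh$w)) / sqrt(pi)
  }
  stats::uniroot(function(a) mean_response(a) - target_incidence,
                 interval = c(-40, 40), tol = 1e-10)$root
}

#' Bernoulli outcomes from true risks
#'
#' `y_i = 1` iff `u_i <= p_true_i` with `u_i ~ U(0, 1)`.
#'
#' @param p_true vector of true event probabilities in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
generate_outcomes <- function(p_true) {
  if (any(p_true < 0 | p_true > 1)) {
    stop("p_true must lie in [0, 1]", call. = FALSE)
  }
  as.integer(stats::runif(length(p_true)) <= p_true)
}

#' Generate a clustered source population
#'
#' Composes center sizes, center random intercepts `u0 ~ N(0, sigma2_u0)`,
#' the six predictors, the linear predictor `lp = alpha_true + sum(x) + u0`
#' (all true coefficients 1), true risks `p_true = plogis(lp)` and Bernoulli
#' outcomes. The fixed intercept is solved so the marginal incidence equals
#' `config$target_incidence`.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer; when given, `set.seed(seed)` first.
#' @return A tibble with columns `center_id`, `x1`..`x6`, `u0` (the patient's
#'   center effect), `lp`, `p_true`, `y`; attributes `alpha_true` and
#'   `sigma2_u0`.
#' @export
generate_source_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  sizes <- generate_center_sizes(config$n_source_centers,
                                 config$center_size_log_mean,
                                 config$center_size_log_sd)
  sigma_u0 <- sqrt(config$sigma2_u0)
  u0 <- stats::rnorm(config$n_source_centers, 0, sigma_u0)
  center_id <- rep(seq_len(config$n_source_centers), sizes)
  n <- length(center_id)
  X <- generate_predictors(n, center_id, u0, config$corr_x1_u0,
                           sigma_u0 = sigma_u0)
  alpha_true <- solve_intercept(config$target_incidence, config$icc,
                                config$corr_x1_u0)
  lp <- alpha_true + as.vector(X %*% BETA_TRUE) + u0[center_id]
  p_true <- stats::plogis(lp)
  pop <- tibble::as_tibble(as.data.frame(X))
  pop <- tibble::add_column(pop, center_id = center_id, .before = 1)
  pop$u0 <- u0[center_id]
  pop$lp <- lp
  pop$p_true <- p_true
  pop$y <- generate_outcomes(p_true)
  attr(pop, "alpha_true") <- alpha_true
  attr(pop, "sigma2_u0") <- config$sigma2_u0
  pop
}

#' Two-stage study sample: centers first, then pooled patients
#'
#' Draws `n_centers` centers by simple random sampling without replacement,
#' then `n_patients` patients by simple random sampling without replacement
#' from the pooled patients of the drawn centers (larger centers therefore
#' contribute proportionally more patients).
#'
#' @param pop a source population from [generate_source_population()] (any
#'   data frame with a `center_id` column works).
#' @param n_centers,n_patients sample dimensions.
#' @return A tibble with the same columns as `pop` plus `.source_row`, the
#'   row index of each sampled patient in `pop`.
#' @export
two_stage_sample <- function(pop, n_centers, n_patients) {
  centers <- unique(pop$center_id)
  if (n_centers > length(centers)) {
    stop("n_centers exceeds the number of centers in the population",
         call. = FALSE)
  }
  drawn <- sample(centers, n_centers)
  pool <- which(pop$center_id %in% drawn)
  if (n_patients > length(pool)) {
    stop(sprintf(
      "n_patients (%d) exceeds the %d patients in the sampled centers",
      n_patients, length(pool)), call. = FALSE)
  }
  rows <- if (n_patients == length(pool)) pool else sample(pool, n_patients)
  out <- pop[rows, , drop = FALSE]
  out$.source_row <- rows
  out
}
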