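# Random-intercept logistic regression (logistic GLMM) and the mixed-effect
# recalibration models used for within-cluster calibration. Estimation is
# delegated to lme4::glmer with adaptive Gauss-Hermite quadrature; an
# independent non-adaptive quadrature evaluator of the marginal likelihood is
# provided for audit (glmm_marginal_loglik).

#' Fit a logistic regression model with a normal random intercept
#'
#' Maximizes the likelihood marginalized over a cluster-level intercept
#' `u_0j ~ N(0, sigma2_u0)` using [lme4::glmer()] with adaptive Gauss-Hermite
#' quadrature (15 nodes by default). Empirical-Bayes cluster effects
#' `u0_hat[j]` are the conditional (posterior) modes at the MLE; posterior
#' means are available through [eb_u0()].
#'
#' A boundary fit (`sigma2_u0 = 0`) is a legitimate result, reported with
#' `boundary = TRUE`, not an error.
#'
#' @param X predictor matrix (no intercept column), or `NULL`.
#' @param y 0/1 outcome vector.
#' @param cluster cluster identifier per observation.
#' @param offset optional log-odds offset.
#' @param nAGQ number of adaptive quadrature nodes (1 = Laplace).
#' @return An object of class `ranint_fit`: `alpha`, `beta`, `sigma2_u0`,
#'   `se` (fixed effects, intercept first), `u0_hat` (named by cluster),
#'   `loglik` (marginal), `converged`, `boundary`, `messages`, and the
#'   underlying `glmerMod` object as `fit`.
#' @export
fit_random_intercept_logistic <- function(X, y, cluster, offset = NULL,
                                          nAGQ = 15) {
  y <- check_binary_outcome(y)
  cl <- factor(cluster)
  if (!is.null(X)) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    dat <- data.frame(.y = y, .cluster = cl, X, check.names = FALSE)
    rhs <- c(sprintf("`%s`", colnames(X)), "(1 | .cluster)")
  } else {
    dat <- data.frame(.y = y, .cluster = cl)
    rhs <- "(1 | .cluster)"
  }
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  if (nlevels(cl) < 2) {
    # degenerate: a single cluster cannot identify sigma2; fall back to the
    # fixed-effects fit with sigma2 = 0
    sf <- fit_standard_logistic(X, y, offset = offset)
    return(structure(
      list(alpha = sf$alpha, beta = sf$beta, sigma2_u0 = 0, se = sf$se,
           u0_hat = stats::setNames(0, levels(cl)), loglik = sf$loglik,
           converged = sf$converged, boundary = TRUE,
           messages = "single cluster: sigma2 fixed at 0", fit = sf$fit),
      class = "ranint_fit"
    ))
  }
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = dat, family = stats::binomial(), nAGQ = nAGQ,
                offset = offset),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  cf <- lme4::fixef(fit)
  sigma2 <- as.numeric(lme4::VarCorr(fit)$.cluster)
  re <- lme4::ranef(fit)$.cluster
  opt_ok <- isTRUE(fit@optinfo$conv$opt == 0)
  hard_fail <- any(grepl("failed to converge", c(msgs,
    unlist(fit@optinfo$conv$lme4$messages)), fixed = TRUE))
  structure(
    list(
      alpha = unname(cf[1]),
      beta = if (length(cf) > 1) cf[-1] else numeric(0),
      sigma2_u0 = sigma2,
      se = sqrt(diag(as.matrix(stats::vcov(fit)))),
      u0_hat = stats::setNames(re[, 1], rownames(re)),
      loglik = as.numeric(stats::logLik(fit)),
      converged = opt_ok && !hard_fail,
      boundary = sigma2 < 1e-8,
      messages = msgs,
      fit = fit
    ),
    class = "ranint_fit"
  )
}

#' @export
print.ranint_fit <- function(x, ...) {
  cat("Random-intercept logistic regression fit\n")
  est <- c("(Intercept)" = x$alpha, x$beta)
  print(cbind(estimate = est, se = x$se))
  cat(sprintf("sigma2_u0 = %.4f (ICC %.3f)%s; logLik %.3f; converged: %s\n",
              x$sigma2_u0, icc_from_variance(x$sigma2_u0),
              if (x$boundary) " [boundary]" else "", x$loglik, x$converged))
  invisible(x)
}

#' Empirical-Bayes cluster-intercept predictions
#'
#' Posterior modes (the default, as stored in the fit) or posterior means of
#' each cluster's random intercept given its data at the MLE. Means are
#' computed by non-adaptive Gauss-Hermite quadrature over the cluster
#' posterior.
#'
#' @param object a `ranint_fit`.
#' @param type `"mode"` or `"mean"`.
#' @param nodes quadrature nodes for `type = "mean"`.
#' @return Named vector of cluster-effect predictions.
#' @export
eb_u0 <- function(object, type = c("mode", "mean"), nodes = 101) {
  type <- match.arg(type)
  if (type == "mode") return(object$u0_hat)
  if (object$sigma2_u0 < 1e-12) {
    return(stats::setNames(rep(0, length(object$u0_hat)), names(object$u0_hat)))
  }
  dat <- stats::model.frame(object$fit)
  eta0 <- compute_fixed_lp(object, dat)
  y <- stats::model.response(dat)
  cl <- dat$.cluster
  gh <- pracma::gaussHermite(nodes)
  u_k <- sqrt(2 * object$sigma2_u0) * gh$x
  lw <- log(gh$w) - 0.5 * log(pi)
  out <- vapply(names(object$u0_hat), function(g) {
    i <- which(cl == g)
    llk <- vapply(u_k, function(u) {
      sum(stats::plogis((2 * y[i] - 1) * (eta0[i] + u), log.p = TRUE))
    }, numeric(1))
    w <- exp(lw + llk - max(lw + llk))
    sum(w * u_k) / sum(w)
  }, numeric(1))
  out
}

compute_fixed_lp <- function(object, dat) {
  if (length(object$beta) == 0) {
    eta <- rep(object$alpha, nrow(dat))
  } else {
    Xm <- as.matrix(dat[, names(object$beta), drop = FALSE])
    eta <- object$alpha + as.vector(Xm %*% object$beta)
  }
  off <- stats::model.offset(dat)
  if (!is.null(off)) eta <- eta + off
  eta
}

#' Marginal log-likelihood of a random-intercept logistic model
#'
#' Independent evaluator of the marginal likelihood at given parameter
#' values, by non-adaptive Gauss-Hermite quadrature over the random intercept
#' (log-sum-exp per cluster). Used to audit the adaptive-quadrature fit:
#' at the MLE it should agree with the fitted `loglik` to high accuracy.
#'
#' @param alpha,beta,sigma2 parameter values (beta may be `numeric(0)`).
#' @param X,y,cluster data as in [fit_random_intercept_logistic()].
#' @param offset optional log-odds offset.
#' @param nodes number of quadrature nodes.
#' @return The marginal log-likelihood (a scalar).
#' @export
glmm_marginal_loglik <- function(alpha, beta, sigma2, X, y, cluster,
                                 offset = NULL, nodes = 101) {
  y <- check_binary_outcome(y)
  eta0 <- rep(alpha, length(y))
  if (length(beta) > 0) eta0 <- eta0 + as.vector(as.matrix(X) %*% beta)
  if (!is.null(offset)) eta0 <- eta0 + offset
  if (sigma2 < 1e-14) {
    return(sum(stats::plogis((2 * y - 1) * eta0, log.p = TRUE)))
  }
  gh <- pracma::gaussHermite(nodes)
  u_k <- sqrt(2 * sigma2) * gh$x
  lw <- log(gh$w) - 0.5 * log(pi)
  s <- (2 * y - 1)
  sum(vapply(split(seq_along(y), cluster), function(i) {
    llk <- vapply(u_k, function(u) {
      sum(stats::plogis(s[i] * (eta0[i] + u), log.p = TRUE))
    }, numeric(1))
    m <- max(lw + llk)
    m + log(sum(exp(lw + llk - m)))
  }, numeric(1)))
}

#' Wald confidence interval for the random-intercept variance
#'
#' Standard error of the variance on the log scale from a central-difference
#' Hessian of the glmer deviance over (theta, fixed effects), delta-method
#' transformed; the interval is exponentiated back. (A profile-likelihood
#' interval is not provided.)
#'
#' @param object a `ranint_fit` with a positive variance estimate.
#' @param level confidence level.
#' @return List with `sigma2_u0`, `se_log_sigma2`, `lower`, `upper`.
#' @export
ranint_variance_ci <- function(object, level = 0.95) {
  stopifnot(inherits(object, "ranint_fit"))
  if (object$boundary) {
    stop("variance estimate is on the boundary (0); no Wald interval",
         call. = FALSE)
  }
  dfun <- stats::update(object$fit, devFunOnly = TRUE)
  theta <- lme4::getME(object$fit, "theta")
  pars <- c(theta, lme4::fixef(object$fit))
  H <- pracma::hessian(function(p) dfun(p), pars)
  V <- 2 * solve(H)                       # deviance = -2 loglik
  se_theta <- sqrt(V[1, 1])
  se_log_s2 <- 2 * se_theta / theta       # log sigma2 = 2 log theta
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(
    sigma2_u0 = object$sigma2_u0,
    se_log_sigma2 = unname(se_log_s2),
    lower = unname(object$sigma2_u0 * exp(-z * se_log_s2)),
    upper = unname(object$sigma2_u0 * exp(z * se_log_s2))
  )
}

# ---- mixed-effect recalibration models ------------------------------------

#' Within-cluster calibration-in-the-large (mixed-effect offset model)
#'
#' Fits `y ~ 1 + (1 | cluster)` with the supplied linear predictor as offset.
#' The fixed intercept is the average within-cluster calibration-in-the-large
#' and the random-intercept SD its between-cluster spread — the "mean (SD)"
#' pair of the within-cluster calibration-intercept rows.
#'
#' @param lp linear predictor (log-odds) used as offset.
#' @param y 0/1 outcomes.
#' @param cluster cluster ids.
#' @param nAGQ adaptive quadrature nodes.
#' @return Object of class `mixed_cal_fit`: `fixed` (named vector), `re_sd`,
#'   `converged`.
#' @export
fit_mixed_calibration_large <- function(lp, y, cluster, nAGQ = 15) {
  stopifnot(all(is.finite(lp)))
  y <- check_binary_outcome(y)
  cl <- factor(cluster)
  if (nlevels(cl) < 2) {
    sf <- fit_standard_logistic(NULL, y, offset = lp)
    return(structure(list(fixed = c(intercept = sf$alpha),
                          re_sd = c(intercept = 0), converged = sf$converged),
                     class = "mixed_cal_fit"))
  }
  dat <- data.frame(.y = y, .cluster = cl, .lp = lp)
  res <- quiet_glmer(.y ~ 1 + (1 | .cluster), dat, offset = lp, nAGQ = nAGQ)
  structure(
    list(fixed = c(intercept = unname(lme4::fixef(res$fit)[1])),
         re_sd = c(intercept = attr(lme4::VarCorr(res$fit)$.cluster, "stddev")[[1]]),
         converged = res$converged),
    class = "mixed_cal_fit"
  )
}

#' Within-cluster calibration slope (mixed-effect recalibration model)
#'
#' Fits `y ~ lp + (1 | cluster) + (0 + lp | cluster)` — random intercept and
#' random slope with independent (diagonal) covariance, by the Laplace
#' approximation. The fixed slope is the average within-cluster calibration
#' slope; the random-slope SD its between-cluster spread.
#'
#' @inheritParams fit_mixed_calibration_large
#' @return Object of class `mixed_cal_fit`: `fixed` (intercept, slope),
#'   `re_sd` (intercept, slope), `converged`.
#' @export
fit_mixed_calibration_slope <- function(lp, y, cluster) {
  stopifnot(all(is.finite(lp)))
  if (stats::var(lp) <= 0) {
    stop("lp must have positive variance to estimate a calibration slope",
         call. = FALSE)
  }
  y <- check_binary_outcome(y)
  cl <- factor(cluster)
  if (nlevels(cl) < 2) {
    sf <- fit_standard_logistic(matrix(lp, ncol = 1, dimnames = list(NULL, ".lp")), y)
    return(structure(list(
      fixed = c(intercept = sf$alpha, slope = unname(sf$beta[1])),
      re_sd = c(intercept = 0, slope = 0), converged = sf$converged),
      class = "mixed_cal_fit"))
  }
  dat <- data.frame(.y = y, .cluster = cl, .lp = lp)
  res <- quiet_glmer(.y ~ .lp + (1 | .cluster) + (0 + .lp | .cluster), dat,
                     offset = NULL, nAGQ = 1)
  vc <- lme4::VarCorr(res$fit)
  sds <- vapply(vc, function(v) attr(v, "stddev")[[1]], numeric(1))
  # terms come back named .cluster / .cluster.1; first is the intercept term
  structure(
    list(fixed = c(intercept = unname(lme4::fixef(res$fit)[1]),
                   slope = unname(lme4::fixef(res$fit)[2])),
         re_sd = c(intercept = unname(sds[1]), slope = unname(sds[2])),
         converged = res$converged),
    class = "mixed_cal_fit"
  )
}

quiet_glmer <- function(form, dat, offset, nAGQ) {
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(form, data = dat, family = stats::binomial(), nAGQ = nAGQ,
                offset = offset),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  hard_fail <- any(grepl("failed to converge", c(msgs,
    unlist(fit@optinfo$conv$lme4$messages)), fixed = TRUE))
  list(fit = fit, converged = isTRUE(fit@optinfo$conv$opt == 0) && !hard_fail,
       messages = msgs)
}

#' @export
print.mixed_cal_fit <- function(x, ...) {
  cat("Mixed-effect recalibration fit\n")
  cat("  fixed:", paste(sprintf("%s = %.4f", names(x$fixed), x$fixed),
                        collapse = ", "), "\n")
  cat("  random-effect SD:", paste(sprintf("%s = %.4f", names(x$re_sd), x$re_sd),
                                   collapse = ", "), "\n")
  cat("  converged:", x$converged, "\n")
  invisible(x)
}
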