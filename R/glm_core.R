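# Standard (fixed-effects-only) logistic regression, with the offset support
# the calibration measures need. Fitting is delegated to stats::glm; this
# layer adds the container, separation diagnostics and prediction interface
# the rest of the pipeline works with.

#' Fit a standard logistic regression model
#'
#' Maximum-likelihood logistic regression via [stats::glm()] with a logit
#' link. An intercept is always included; `X = NULL` fits an intercept-only
#' model (the form used for calibration-in-the-large, with `offset` set to a
#' model's linear predictor).
#'
#' Quasi-separation is flagged: if any fitted linear predictor exceeds 30 in
#' absolute value, `converged` is `FALSE` and `separation` is `TRUE`, so the
#' simulation runner can exclude the replication.
#'
#' @param X predictor matrix/data frame (columns are predictors; no intercept
#'   column), or `NULL` for intercept-only.
#' @param y 0/1 outcome vector.
#' @param offset optional per-observation offset on the log-odds scale.
#' @return An object of class `standard_fit`: a list with `alpha` (intercept),
#'   `beta` (named coefficient vector), `se` (intercept first), `loglik`,
#'   `converged`, `separation`, `n_iter`, and the underlying `glm` object as
#'   `fit`.
#' @export
fit_standard_logistic <- function(X, y, offset = NULL) {
  y <- check_binary_outcome(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    stopifnot(nrow(X) == length(y))
    if (nrow(X) <= ncol(X)) {
      stop("need more observations than parameters", call. = FALSE)
    }
    dat <- data.frame(.y = y, X, check.names = FALSE)
    form <- stats::reformulate(sprintf("`%s`", colnames(X)), response = ".y")
  } else {
    dat <- data.frame(.y = y)
    form <- .y ~ 1
  }
  fit <- stats::glm(form, family = stats::binomial(), data = dat,
                    offset = offset,
                    control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  cf <- stats::coef(fit)
  # |lp| > 15 means a fitted probability within ~1e-7 of 0 or 1: the
  # signature of (quasi-)separation under glm's stopping rule
  separation <- any(abs(fit$linear.predictors) > 15)
  structure(
    list(
      alpha = unname(cf[1]),
      beta = if (length(cf) > 1) cf[-1] else numeric(0),
      se = sqrt(diag(stats::vcov(fit))),
      loglik = as.numeric(stats::logLik(fit)),
      converged = fit$converged && !separation,
      separation = separation,
      n_iter = fit$iter,
      fit = fit
    ),
    class = "standard_fit"
  )
}

#' @export
print.standard_fit <- function(x, ...) {
  cat("Standard logistic regression fit\n")
  est <- c("(Intercept)" = x$alpha, x$beta)
  print(cbind(estimate = est, se = x$se,
              `lower95` = est - 1.96 * x$se, `upper95` = est + 1.96 * x$se))
  cat(sprintf("logLik %.3f; converged: %s%s\n", x$loglik, x$converged,
              if (x$separation) " (separation detected)" else ""))
  invisible(x)
}

#' Coefficient table for a fitted model
#'
#' Estimates with Wald 95% confidence intervals, one row per coefficient.
#'
#' @param fit a `standard_fit` or `ranint_fit`.
#' @return A tibble with columns `term`, `estimate`, `se`, `lower95`, `upper95`.
#' @export
coef_table <- function(fit) {
  est <- c("(Intercept)" = fit$alpha, fit$beta)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(fit$se[seq_along(est)]),
    lower95 = unname(est - 1.96 * fit$se[seq_along(est)]),
    upper95 = unname(est + 1.96 * fit$se[seq_along(est)])
  )
}

check_binary_outcome <- function(y) {
  y <- as.integer(y)
  if (anyNA(y) || !all(y %in% c(0L, 1L))) {
    stop("y must be a 0/1 vector without missing values", call. = FALSE)
  }
  y
}
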