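# The three per-patient risk calculations: standard (standard logistic
# model), marginal (fixed effects of the random-intercept model only) and
# conditional (fixed effects plus the cluster's empirical-Bayes intercept).

new_risk_vector <- function(mode, lp) {
  structure(list(mode = mode, lp = as.numeric(lp),
                 p = stats::plogis(as.numeric(lp))),
            class = "risk_vector")
}

#' @export
print.risk_vector <- function(x, ...) {
  cat(sprintf("Risk vector (%s): %d patients, mean p = %.3f, sd(lp) = %.3f\n",
              x$mode, length(x$p), mean(x$p), stats::sd(x$lp)))
  invisible(x)
}

design_lp <- function(alpha, beta, X) {
  if (length(beta) == 0) return(rep(alpha, nrow(as.matrix(X))))
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && all(names(beta) %in% colnames(X))) {
    X <- X[, names(beta), drop = FALSE]
  }
  if (ncol(X) != length(beta)) {
    stop(sprintf("design has %d columns but the model has %d coefficients",
                 ncol(X), length(beta)), call. = FALSE)
  }
  alpha + as.vector(X %*% beta)
}

#' Predicted risks from the standard logistic model
#'
#' `lp = alpha + X beta` from the standard fit; `p = plogis(lp)`.
#'
#' @param fit a `standard_fit`.
#' @param X predictor matrix matching the fit's coefficients.
#' @return A `risk_vector` (mode `"standard"`) with elements `lp` and `p`.
#' @export
predict_standard <- function(fit, X) {
  stopifnot(inherits(fit, "standard_fit"))
  new_risk_vector("standard", design_lp(fit$alpha, fit$beta, X))
}

#' Marginal risk calculation from the random-intercept model
#'
#' Uses only the fixed effects of the random-intercept fit; the cluster
#' effects are deliberately ignored, so the calculation applies to patients
#' from clusters never seen at development.
#'
#' @param fit a `ranint_fit`.
#' @param X predictor matrix matching the fit's fixed effects.
#' @return A `risk_vector` (mode `"marginal"`).
#' @export
predict_marginal <- function(fit, X) {
  stopifnot(inherits(fit, "ranint_fit"))
  new_risk_vector("marginal", design_lp(fit$alpha, fit$beta, X))
}

#' Conditional risk calculation from the random-intercept model
#'
#' Adds each patient's cluster empirical-Bayes intercept `u0_hat[j]` to the
#' fixed-effect linear predictor. Patients from clusters absent at
#' development have no estimated effect: such input is an error (use the
#' marginal calculation for new clusters).
#'
#' @param fit a `ranint_fit`.
#' @param X predictor matrix matching the fit's fixed effects.
#' @param cluster cluster id per row of `X`; every id must appear in
#'   `fit$u0_hat`.
#' @return A `risk_vector` (mode `"conditional"`).
#' @export
predict_conditional <- function(fit, X, cluster) {
  stopifnot(inherits(fit, "ranint_fit"))
  key <- as.character(cluster)
  unseen <- setdiff(unique(key), names(fit$u0_hat))
  if (length(unseen) > 0) {
    stop(sprintf(
      "cluster(s) %s were not in the development data; the conditional risk calculation is undefined for them",
      paste(unseen, collapse = ", ")), call. = FALSE)
  }
  lp <- design_lp(fit$alpha, fit$beta, X) + unname(fit$u0_hat[key])
  new_risk_vector("conditional", lp)
}
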