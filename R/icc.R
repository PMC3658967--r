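#' Random-intercept variance implied by a latent-scale ICC
#'
#' On the latent logistic scale the residual variance is \eqn{\pi^2/3}, so an
#' intraclass correlation \eqn{\rho} corresponds to a random-intercept
#' variance \eqn{\sigma^2_{u0} = \rho \, (\pi^2/3) / (1 - \rho)}.
#'
#' @param icc intraclass correlation, in `[0, 1)`.
#' @return Random-intercept variance in squared log-odds.
#' @seealso [icc_from_variance()] for the inverse.
#' @export
#' @examples
#' variance_from_icc(0.05)
#' icc_from_variance(variance_from_icc(0.15))
variance_from_icc <- function(icc) {
  stopifnot(is.numeric(icc))
  if (any(icc < 0) || any(icc >= 1)) {
    stop("`icc` must lie in [0, 1)", call. = FALSE)
  }
  icc * (pi^2 / 3) / (1 - icc)
}

#' Latent-scale ICC implied by a random-intercept variance
#'
#' @param sigma2_u0 random-intercept variance (log-odds squared), >= 0.
#' @return Intraclass correlation \eqn{\sigma^2_{u0} / (\sigma^2_{u0} + \pi^2/3)}.
#' @export
icc_from_variance <- function(sigma2_u0) {
  stopifnot(is.numeric(sigma2_u0))
  if (any(sigma2_u0 < 0)) {
    stop("`sigma2_u0` must be non-negative", call. = FALSE)
  }
  sigma2_u0 / (sigma2_u0 + pi^2 / 3)
}
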