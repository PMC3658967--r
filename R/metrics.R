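# Performance battery: overall and within-cluster discrimination (Harrell's
# c-index) and calibration (calibration-in-the-large, calibration slope, and
# their mixed-effect within-cluster versions).

#' Harrell's concordance index for binary outcomes
#'
#' Fraction of (event, non-event) pairs in which the event patient has the
#' higher predicted risk; tied predictions score 0.5. Computed with midranks
#' (the Mann-Whitney identity), i.e. O(n log n).
#'
#' @param p predicted risks (any monotone score works).
#' @param y 0/1 outcomes; both classes must be present.
#' @return Concordance in `[0, 1]`.
#' @export
c_index <- function(p, y) {
  y <- check_binary_outcome(y)
  stopifnot(length(p) == length(y))
  n1 <- as.numeric(sum(y == 1L))
  n0 <- as.numeric(sum(y == 0L))
  if (n1 == 0 || n0 == 0) {
    stop("c-index undefined: need at least one event and one non-event",
         call. = FALSE)
  }
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Within-cluster c-index: average of the per-cluster c-indices
#'
#' The c-index is computed inside each cluster that contains at least one
#' event and one non-event; clusters without outcome variation are excluded
#' and counted. The summary is the unweighted mean and the between-cluster SD
#' of the per-cluster c-indices (a size-weighted mean is available).
#'
#' @param p predicted risks.
#' @param y 0/1 outcomes.
#' @param cluster cluster ids.
#' @param weighted if `TRUE`, weight cluster c-indices by cluster size.
#' @return List with `mean`, `sd`, `n_clusters_used`, `n_clusters_excluded`,
#'   and the per-cluster values `by_cluster`.
#' @export
c_index_within <- function(p, y, cluster, weighted = FALSE) {
  y <- check_binary_outcome(y)
  idx <- split(seq_along(y), cluster)
  usable <- vapply(idx, function(i) any(y[i] == 1L) && any(y[i] == 0L),
                   logical(1))
  if (!any(usable)) {
    stop("no cluster has both an event and a non-event", call. = FALSE)
  }
  cs <- vapply(idx[usable], function(i) c_index(p[i], y[i]), numeric(1))
  w <- if (weighted) lengths(idx[usable]) else rep(1, length(cs))
  list(
    mean = sum(w * cs) / sum(w),
    sd = stats::sd(cs),
    n_clusters_used = length(cs),
    n_clusters_excluded = sum(!usable),
    by_cluster = cs
  )
}

#' Calibration-in-the-large
#'
#' Intercept of a logistic regression of the outcome with the linear
#' predictor as offset. 0 means predicted and observed event rates agree on
#' average; positive values mean risks are under-predicted.
#'
#' @param lp linear predictor (log-odds) of the risk calculation.
#' @param y 0/1 outcomes.
#' @return The offset-model intercept (log-odds).
#' @export
calibration_in_the_large <- function(lp, y) {
  stopifnot(all(is.finite(lp)))
  fit_standard_logistic(NULL, y, offset = lp)$alpha
}

#' Calibration slope
#'
#' Slope of a logistic regression of the outcome on the linear predictor
#' (with a free intercept). 1 is ideal; < 1 indicates overfitting.
#'
#' @inheritParams calibration_in_the_large
#' @return The slope (dimensionless).
#' @export
calibration_slope <- function(lp, y) {
  stopifnot(all(is.finite(lp)))
  if (stats::var(lp) <= 0) {
    stop("lp must have positive variance to estimate a calibration slope",
         call. = FALSE)
  }
  unname(fit_standard_logistic(matrix(lp, ncol = 1,
                                      dimnames = list(NULL, "lp")), y)$beta[1])
}

#' Full performance battery for one risk vector
#'
#' Assembles overall and within-cluster discrimination and calibration:
#' overall c-index, within-cluster c (mean and between-cluster SD),
#' calibration-in-the-large and slope overall, and — via the mixed-effect
#' recalibration models — within clusters (fixed effect and random-effect SD
#' for each). The within-cluster calibration models are the expensive part
#' and can be switched off for large test populations.
#'
#' @param risk a `risk_vector`.
#' @param y 0/1 outcomes aligned with `risk`.
#' @param cluster cluster ids aligned with `risk`.
#' @param within_c compute the within-cluster c-index summary.
#' @param within_calibration fit the mixed-effect recalibration models.
#' @return One-row tibble with columns `mode`, `c_overall`, `c_within_mean`,
#'   `c_within_sd`, `n_clusters_used`, `citl_overall`, `citl_within_fixed`,
#'   `citl_within_sd`, `slope_overall`, `slope_within_fixed`,
#'   `slope_within_sd`, `cal_converged`.
#' @export
evaluate_performance <- function(risk, y, cluster,
                                 within_c = TRUE, within_calibration = TRUE) {
  stopifnot(inherits(risk, "risk_vector"))
  y <- check_binary_outcome(y)
  stopifnot(length(risk$p) == length(y), length(cluster) == length(y))
  out <- tibble::tibble(
    mode = risk$mode,
    c_overall = c_index(risk$p, y),
    c_within_mean = NA_real_, c_within_sd = NA_real_,
    n_clusters_used = NA_integer_,
    citl_overall = calibration_in_the_large(risk$lp, y),
    citl_within_fixed = NA_real_, citl_within_sd = NA_real_,
    slope_overall = calibration_slope(risk$lp, y),
    slope_within_fixed = NA_real_, slope_within_sd = NA_real_,
    cal_converged = TRUE
  )
  if (within_c) {
    cw <- c_index_within(risk$p, y, cluster)
    out$c_within_mean <- cw$mean
    out$c_within_sd <- cw$sd
    out$n_clusters_used <- as.integer(cw$n_clusters_used)
  }
  if (within_calibration) {
    large <- fit_mixed_calibration_large(risk$lp, y, cluster)
    slope <- fit_mixed_calibration_slope(risk$lp, y, cluster)
    out$citl_within_fixed <- unname(large$fixed["intercept"])
    out$citl_within_sd <- unname(large$re_sd["intercept"])
    out$slope_within_fixed <- unname(slope$fixed["slope"])
    out$slope_within_sd <- unname(slope$re_sd["slope"])
    out$cal_converged <- large$converged && slope$converged
  }
  out
}
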