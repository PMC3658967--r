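# Simulation-study orchestration: one replication = generate a source
# population, draw a two-stage sample, fit both models, evaluate the three
# risk calculations in the sample (apparent) and the standard + marginal
# calculations in the full source population (test). Scenarios repeat this
# and aggregate into paper-style tables.

MEASURE_COLS <- c("c_overall", "c_within_mean", "c_within_sd",
                  "n_clusters_used", "citl_overall", "citl_within_fixed",
                  "citl_within_sd", "slope_overall", "slope_within_fixed",
                  "slope_within_sd", "cal_converged")

#' Run one simulation replication
#'
#' Seeds the RNG at `base_seed + rep_index`, generates a source population
#' (unless one is supplied), draws the two-stage study sample, fits the
#' standard and random-intercept models, and evaluates: apparent performance
#' of the standard, marginal and conditional risk calculations in the sample,
#' and test performance of the standard and marginal calculations in the full
#' source population. The conditional calculation has no test entries: the
#' source population's unsampled clusters have no estimated effects.
#'
#' @param config a [scenario_config()].
#' @param rep_index replication number (>= 1).
#' @param pop optional pre-generated source population (used with a fixed
#'   population across replications); by default a fresh one is generated.
#' @param test evaluate test performance in the source population.
#' @param test_within_calibration fit the mixed-effect within-cluster
#'   calibration models on the full source population too (slow; the
#'   full-table reproduction needs it, summary measures do not).
#' @return Tibble of performance rows (one per model x phase) with
#'   replication metadata: `rep`, `phase`, `model`, the measure columns,
#'   `fit_converged`, `sigma2_u0_hat`.
#' @export
run_replication <- function(config, rep_index, pop = NULL, test = TRUE,
                            test_within_calibration = FALSE) {
  set.seed(config$base_seed + rep_index)
  if (is.null(pop)) pop <- generate_source_population(config)
  samp <- two_stage_sample(pop, config$n_sample_centers,
                           config$n_sample_patients)
  xcols <- paste0("x", 1:6)
  Xs <- as.matrix(samp[, xcols])
  std <- fit_standard_logistic(Xs, samp$y)
  re <- fit_random_intercept_logistic(Xs, samp$y, samp$center_id)
  ok <- std$converged && re$converged
  risks <- list(
    standard = predict_standard(std, Xs),
    marginal = predict_marginal(re, Xs),
    conditional = predict_conditional(re, Xs, samp$center_id)
  )
  rows <- lapply(names(risks), function(m) {
    perf <- evaluate_performance(risks[[m]], samp$y, samp$center_id)
    tibble::add_column(perf[, MEASURE_COLS],
                       rep = rep_index, phase = "apparent", model = m,
                       .before = 1)
  })
  if (test) {
    Xp <- as.matrix(pop[, xcols])
    test_risks <- list(
      standard = predict_standard(std, Xp),
      marginal = predict_marginal(re, Xp)
    )
    rows <- c(rows, lapply(names(test_risks), function(m) {
      perf <- evaluate_performance(
        test_risks[[m]], pop$y, pop$center_id,
        within_calibration = test_within_calibration)
      tibble::add_column(perf[, MEASURE_COLS],
                         rep = rep_index, phase = "test", model = m,
                         .before = 1)
    }))
  }
  out <- do.call(rbind, rows)
  out$fit_converged <- ok
  out$sigma2_u0_hat <- re$sigma2_u0
  out
}

#' Run a full simulation scenario
#'
#' Repeats [run_replication()] `reps` times (per-replication seeds
#' `base_seed + 1 .. base_seed + reps`) and aggregates across the converged
#' replications. By default each replication generates its own source
#' population; `fixed_population = TRUE` generates one at `base_seed` and
#' reuses it.
#'
#' @param config a [scenario_config()].
#' @param reps number of replications (default `config$n_reps`).
#' @param test,test_within_calibration passed to [run_replication()].
#' @param fixed_population reuse a single source population.
#' @param verbose print a progress line per replication.
#' @return Object of class `scenario_result`: list with `config`, `per_rep`
#'   (all replication rows), `summary` (aggregates, see
#'   [aggregate_replications()]), `n_reps`, `n_nonconverged`, `unreliable`
#'   (`TRUE` when more than 20% of replications failed to converge).
#' @export
run_scenario <- function(config, reps = config$n_reps, test = TRUE,
                         test_within_calibration = FALSE,
                         fixed_population = FALSE, verbose = FALSE) {
  pop <- NULL
  if (fixed_population) {
    set.seed(config$base_seed)
    pop <- generate_source_population(config)
  }
  per_rep <- vector("list", reps)
  for (r in seq_len(reps)) {
    per_rep[[r]] <- run_replication(config, r, pop = pop, test = test,
                                    test_within_calibration = test_within_calibration)
    if (verbose) {
      message(sprintf("rep %d/%d%s", r, reps,
                      if (per_rep[[r]]$fit_converged[1]) "" else "  [non-converged]"))
    }
  }
  per_rep <- do.call(rbind, per_rep)
  n_bad <- length(unique(per_rep$rep[!per_rep$fit_converged]))
  structure(
    list(
      config = config,
      per_rep = per_rep,
      summary = aggregate_replications(per_rep),
      n_reps = reps,
      n_nonconverged = n_bad,
      unreliable = n_bad > 0.2 * reps
    ),
    class = "scenario_result"
  )
}

#' Aggregate per-replication performance rows
#'
#' Converged replications only. Overall c-index: mean and 2.5/97.5
#' percentiles across replications. Within-cluster c: mean of the per-sample
#' means and mean of the per-sample between-cluster SDs. Calibration rows:
#' means of the estimates (fixed effect and random-effect SD for the
#' within-cluster versions).
#'
#' @param per_rep replication rows as produced by [run_replication()].
#' @return Tibble with one row per phase x model.
#' @export
aggregate_replications <- function(per_rep) {
  keep <- per_rep[per_rep$fit_converged, , drop = FALSE]
  groups <- unique(keep[, c("phase", "model")])
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    d <- keep[keep$phase == groups$phase[g] & keep$model == groups$model[g], ]
    tibble::tibble(
      phase = groups$phase[g],
      model = groups$model[g],
      n_reps_used = nrow(d),
      c_mean = mean(d$c_overall),
      c_lo = unname(stats::quantile(d$c_overall, 0.025)),
      c_hi = unname(stats::quantile(d$c_overall, 0.975)),
      c_within_mean = mean(d$c_within_mean),
      c_within_sd = mean(d$c_within_sd),
      citl = mean(d$citl_overall),
      citl_within = mean(d$citl_within_fixed),
      citl_within_sd = mean(d$citl_within_sd),
      slope = mean(d$slope_overall),
      slope_within = mean(d$slope_within_fixed),
      slope_within_sd = mean(d$slope_within_sd)
    )
  })
  do.call(rbind, rows)
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$config)
  cat(sprintf("%d replications, %d non-converged%s\n\n", x$n_reps,
              x$n_nonconverged,
              if (x$unreliable) "  ** UNRELIABLE (>20% exclusions) **" else ""))
  print(format_scenario_table(x))
  invisible(x)
}

#' Paper-style performance table for a scenario
#'
#' Formats a [run_scenario()] result as the familiar six-measure table:
#' rows are overall/within-cluster c-index, calibration intercept and slope;
#' columns are the apparent standard / marginal / conditional calculations
#' and the test standard / marginal calculations. Cells carry the across-
#' replication mean, with the 2.5/97.5 percentile range for the overall
#' c-index and the (SD) companion for the within-cluster rows.
#'
#' @param result a `scenario_result`.
#' @return A data frame of formatted strings, one row per measure.
#' @export
format_scenario_table <- function(result) {
  s <- result$summary
  cols <- list(
    `Standard (apparent)` = c("apparent", "standard"),
    `Marginal (apparent)` = c("apparent", "marginal"),
    `Conditional (apparent)` = c("apparent", "conditional"),
    `Standard (test)` = c("test", "standard"),
    `Marginal (test)` = c("test", "marginal")
  )
  fmt <- function(phase, model) {
    d <- s[s$phase == phase & s$model == model, ]
    if (nrow(d) == 0) return(rep("-", 6))
    c(
      sprintf("%.2f (%.3f; %.3f)", d$c_mean, d$c_lo, d$c_hi),
      sprintf("%.2f (%.3f)", d$c_within_mean, d$c_within_sd),
      sprintf("%.2f", d$citl),
      if (is.na(d$citl_within)) "-" else
        sprintf("%.2f (%.3f)", d$citl_within, d$citl_within_sd),
      sprintf("%.2f", d$slope),
      if (is.na(d$slope_within)) "-" else
        sprintf("%.2f (%.3f)", d$slope_within, d$slope_within_sd)
    )
  }
  tab <- vapply(cols, function(pm) fmt(pm[1], pm[2]), character(6))
  data.frame(
    measure = c("C-index (overall)", "C-index within clusters",
                "Calibration intercept", "Calibration intercept within clusters",
                "Calibration slope", "Calibration slope within clusters"),
    tab, check.names = FALSE
  )
}

# Scenario grid underlying the reproduced simulation tables.
TABLE_SCENARIOS <- list(
  table3 = list(icc = 0.05, corr_x1_u0 = 0),
  table4 = list(icc = 0.15, corr_x1_u0 = 0),
  table5 = list(icc = 0.05, corr_x1_u0 = 0, n_sample_centers = 5,
                n_sample_patients = 100),
  table6 = list(icc = 0.05, corr_x1_u0 = 0, n_sample_centers = 50,
                n_sample_patients = 1000),
  tableS1 = list(icc = 0.05, corr_x1_u0 = 0.4),
  tableS2 = list(icc = 0.15, corr_x1_u0 = 0.4),
  tableS3 = list(icc = 0.30, corr_x1_u0 = 0),
  tableS4 = list(icc = 0.30, corr_x1_u0 = 0.4),
  tableS5 = list(icc = 0.05, corr_x1_u0 = 0, target_incidence = 0.03)
)

#' Reproduce the simulation result tables
#'
#' Runs the named scenarios of the simulation grid — base ICC 5/15/30% with
#' and without predictor-cluster correlation, the 5-center/100-patient and
#' 50-center/1000-patient designs, and the 3%-incidence low-event setting —
#' and writes one delimited table per scenario.
#'
#' @param which scenario ids among `names(TABLE_SCENARIOS)` (`"table3"` ..
#'   `"tableS5"`).
#' @param reps replications per scenario (default 100).
#' @param base_seed base RNG seed; scenario k uses `base_seed + 1000 * k`.
#' @param dir output directory for `<id>.tsv` files (`NULL`: don't write).
#' @param test_within_calibration include the within-cluster calibration rows
#'   of the test columns (slow: mixed models on the full source population).
#' @param verbose print progress.
#' @return Named list of `scenario_result` objects, invisibly if writing.
#' @export
reproduce_tables <- function(which = names(TABLE_SCENARIOS), reps = 100,
                             base_seed = 1, dir = "results",
                             test_within_calibration = TRUE,
                             verbose = interactive()) {
  unknown <- setdiff(which, names(TABLE_SCENARIOS))
  if (length(unknown) > 0) {
    stop("unknown table id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (id in which) {
    k <- match(id, names(TABLE_SCENARIOS))
    args <- c(TABLE_SCENARIOS[[id]],
              list(n_reps = reps, base_seed = base_seed + 1000 * k))
    config <- do.call(scenario_config, args)
    if (verbose) message("Running ", id, " ...")
    res <- run_scenario(config, test_within_calibration = test_within_calibration,
                        verbose = verbose)
    out[[id]] <- res
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      utils::write.table(format_scenario_table(res),
                         file.path(dir, paste0(id, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out)
}

#' Fit both prediction models to a clustered binary dataset
#'
#' Convenience wrapper for applying the pipeline to any clustered dataset (a
#' generated sample or a real cohort read with [read_population()]): fits the
#' standard and the random-intercept logistic model on the named predictor
#' columns.
#'
#' @param data data frame with outcome, cluster and predictor columns.
#' @param predictors character vector of predictor column names.
#' @param outcome,cluster column names of the 0/1 outcome and cluster id.
#' @return List with elements `standard` (a `standard_fit`) and
#'   `random_intercept` (a `ranint_fit`).
#' @export
fit_models <- function(data, predictors, outcome = "y", cluster = "center_id") {
  X <- as.matrix(data[, predictors, drop = FALSE])
  y <- data[[outcome]]
  list(
    standard = fit_standard_logistic(X, y),
    random_intercept = fit_random_intercept_logistic(X, y, data[[cluster]])
  )
}
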