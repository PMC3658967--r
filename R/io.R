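# Delimited-text interfaces: populations/samples as TSV, scenario configs as
# key-value YAML.

#' Write a population or sample as tab-delimited text
#'
#' @param pop data frame from [generate_source_population()] or
#'   [two_stage_sample()].
#' @param path output file.
#' @export
write_population <- function(pop, path) {
  utils::write.table(pop, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clustered binary dataset from delimited text
#'
#' Expects a header row; a `center_id` (or `cluster`) column and a 0/1 `y`
#' column are required for model fitting, anything else is treated as data
#' columns. Populations written by [write_population()] round-trip.
#'
#' @param path input file.
#' @param sep field separator (default tab).
#' @return A tibble.
#' @export
read_population <- function(path, sep = "\t") {
  tibble::as_tibble(utils::read.delim(path, sep = sep, check.names = FALSE))
}

#' Read a scenario configuration from a YAML key-value file
#'
#' Keys mirror the [scenario_config()] arguments; missing keys take the
#' defaults.
#'
#' @param path YAML file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, vals)
}
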