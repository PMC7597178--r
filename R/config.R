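#' Run configuration for the command-line pipeline
#'
#' A nested list of every tunable in the pipeline with its documented
#' default; partial specifications are merged over the defaults.  Round-trips
#' losslessly through YAML via [read_run_config()] / [write_run_config()].
#'
#' @param ... named overrides of the default fields: `embedding` (list with
#'   `k`), `point_pattern` (list with `n_radii`, `r_max`, `correction`,
#'   `c_constant`, `expand_fraction`), `simulation` (list with `n_nodes`,
#'   `block_sizes`, `block_correlations`, `n_time`, `n_subjects`, `mean`),
#'   `analysis` (list with `alpha`, `n_replicates`, `test`), `seed`,
#'   `log_level`.
#' @return a `run_config` list.
#' @export
run_config <- function(...) {
  defaults <- list(
    embedding = list(k = 2L),
    point_pattern = list(n_radii = 100L, r_max = NULL,
                         correction = "translation", c_constant = 1,
                         expand_fraction = 0),
    simulation = list(n_nodes = 100L, block_sizes = c(20L, 30L),
                      block_correlations = c(0.5, 0.6), n_time = 150L,
                      n_subjects = 100L, mean = 0),
    analysis = list(alpha = 0.05, n_replicates = 100L, test = "welch"),
    seed = 1L,
    log_level = "info")
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  merged <- utils::modifyList(defaults, overrides, keep.null = TRUE)
  structure(merged, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  run_config(yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Translate the point_pattern/embedding blocks into a geme_config.
as_geme_config <- function(config) {
  pp <- config$point_pattern
  geme_config(k = config$embedding$k, correction = pp$correction,
              n_radii = pp$n_radii, r_max = pp$r_max,
              c_constant = pp$c_constant,
              expand_fraction = pp$expand_fraction)
}
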