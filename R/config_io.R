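#' Read a scenario or simulation configuration from YAML
#'
#' Plain-YAML serializations of the package's configuration objects, used by
#' the command-line interface. A scenario file mirrors [scenario_spec()]
#' with a nested `condition` block mirroring [reaction_condition()]; a
#' simulation file mirrors [simulation_config()].
#'
#' @param path Path to a YAML file.
#' @return `scenario_from_yaml()` returns a [scenario_spec()];
#'   `simulation_config_from_yaml()` returns a [simulation_config()].
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c(
#'   "condition: {actin_unlabeled: 0.5, actin_labeled: 0.25,",
#'   "  profilin_total: 5, kd_unlabeled: 2.9, kd_labeled: 29}",
#'   "true_k_off: 0.0035",
#'   "elongation_rate_mean: 18.55",
#'   "n_filaments: 100", "seed: 1"), f)
#' scenario_from_yaml(f)
#' @export
scenario_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$condition))
    stop("scenario YAML needs a 'condition' block")
  cond <- do.call(reaction_condition, x$condition)
  x$condition <- NULL
  do.call(scenario_spec, c(list(condition = cond), x))
}

#' @rdname scenario_from_yaml
#' @export
simulation_config_from_yaml <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}
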