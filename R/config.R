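#' Run configuration
#'
#' One structured object drives every command. Exactly one input source must
#' be supplied: either the five CSV paths of a real dataset (`data`) or a
#' synthetic scenario (`scenario`). All numerical defaults (1000 iterations,
#' 95th percentile, HI threshold 1, IR threshold 1e-5, 5 replicates,
#' sensitivity tolerance 0.05, and the laboratory constants) are overridable
#' and are echoed into output metadata.
#'
#' @param data `NULL`, or a named list with paths `samples`, `odor`, `tox`,
#'   `survey`, `presentations`.
#' @param scenario `NULL`, or a [syn_scenario()] (the string `"default"`
#'   selects [default_scenario()]).
#' @param iterations Monte Carlo iterations (>= 1; default 1000).
#' @param master_seed integer master seed (default 1).
#' @param percentile_used acceptability percentile (default 95).
#' @param hi_threshold,ir_threshold acceptability thresholds (> 0).
#' @param replicate_count sensitivity replicates (default 5).
#' @param sensitivity_tolerance maximum acceptable pairwise CDF distance
#'   (default 0.05).
#' @param constants a [lab_constants()] object.
#' @return an object of class `run_config`.
#' @export
run_config <- function(data = NULL, scenario = NULL, iterations = 1000,
                       master_seed = 1, percentile_used = 95,
                       hi_threshold = 1, ir_threshold = 1e-5,
                       replicate_count = 5, sensitivity_tolerance = 0.05,
                       constants = lab_constants()) {
  if (is.null(data) == is.null(scenario)) {
    stop("exactly one of `data` (CSV paths) or `scenario` must be supplied")
  }
  if (!is.null(data)) {
    need <- c("samples", "odor", "tox", "survey", "presentations")
    missing <- setdiff(need, names(data))
    if (length(missing) > 0) {
      stop("data paths missing: ", paste(missing, collapse = ", "))
    }
  }
  if (identical(scenario, "default")) scenario <- default_scenario(master_seed)
  if (!is.null(scenario) && !inherits(scenario, "syn_scenario")) {
    stop("scenario must be a syn_scenario or the string \"default\"")
  }
  if (iterations < 1) stop("iterations must be >= 1")
  if (hi_threshold <= 0 || ir_threshold <= 0) stop("thresholds must be > 0")
  if (percentile_used <= 0 || percentile_used >= 100) {
    stop("percentile_used must lie in (0, 100)")
  }
  stopifnot(inherits(constants, "lab_constants"))
  structure(
    list(data = data, scenario = scenario, iterations = as.integer(iterations),
         master_seed = as.integer(master_seed),
         percentile_used = percentile_used, hi_threshold = hi_threshold,
         ir_threshold = ir_threshold,
         replicate_count = as.integer(replicate_count),
         sensitivity_tolerance = sensitivity_tolerance,
         constants = constants),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; `constants` is a
#' nested mapping of [lab_constants()] fields; `scenario: default` selects
#' the built-in synthetic scenario. Relative data paths are resolved against
#' the YAML file's directory.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  data <- raw$data
  if (!is.null(data)) {
    data <- lapply(data, function(p) {
      if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
    })
  }
  constants <- do.call(lab_constants, as.list(raw$constants %||% list()))
  run_config(
    data = data,
    scenario = raw$scenario,
    iterations = raw$iterations %||% 1000,
    master_seed = raw$master_seed %||% 1,
    percentile_used = raw$percentile_used %||% 95,
    hi_threshold = raw$hi_threshold %||% 1,
    ir_threshold = raw$ir_threshold %||% 1e-5,
    replicate_count = raw$replicate_count %||% 5,
    sensitivity_tolerance = raw$sensitivity_tolerance %||% 0.05,
    constants = constants
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Materialize the configured input source as loaded package objects.
load_config_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$scenario)) {
    ds <- generate_dataset(config$scenario)
    list(
      sample_set = read_sample_set(ds$samples, ds$odor),
      tox = load_tox_table(ds$tox),
      survey = read_panel_survey(ds$survey, ds$presentations),
      dataset = ds
    )
  } else {
    list(
      sample_set = read_sample_set(config$data$samples, config$data$odor),
      tox = load_tox_table(config$data$tox),
      survey = read_panel_survey(config$data$survey, config$data$presentations),
      dataset = NULL
    )
  }
}
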