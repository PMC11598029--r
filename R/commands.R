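#' Fit command: distributions and exclusion report
#'
#' Loads (or generates) the configured dataset, fits every truncated Gaussian
#' spec, and writes `specs.csv` plus `exclusions.csv` to `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return the fitted `risk_model`, invisibly.
#' @export
cmd_fit <- function(config, out_dir = ".") {
  inputs <- load_config_inputs(config)
  model <- fit_risk_model(inputs$sample_set, inputs$tox, inputs$survey,
                          config$constants)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model_spec_table(model), file.path(out_dir, "specs.csv"),
                   row.names = FALSE)
  utils::write.csv(model$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  invisible(model)
}

#' Run command: full Monte Carlo assessment with report files
#'
#' Fits the model and simulates HI and IR for every category, then writes:
#' `results.csv` (3 significant digits, the reporting convention),
#' `results_full.csv` (full precision), one `cdf_<category>_<metric>.csv`
#' and `pdf_<category>_<metric>.csv` point series per computed distribution,
#' `exclusions.csv`, and `run.log` (seeds, iteration counts, exclusions,
#' skipped categories).
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param bins histogram bins for the PDF series (default 30).
#' @return the `risk_assessment`, invisibly.
#' @export
cmd_run <- function(config, out_dir = ".", bins = 30) {
  inputs <- load_config_inputs(config)
  model <- fit_risk_model(inputs$sample_set, inputs$tox, inputs$survey,
                          config$constants)
  assessment <- run_assessment(model, config$iterations, config$master_seed,
                               config$percentile_used, config$hi_threshold,
                               config$ir_threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- assessment_table(assessment)
  full <- tab
  pretty <- tab
  num <- vapply(pretty, is.numeric, logical(1)) &
    !names(pretty) %in% c("iterations", "seed")
  pretty[num] <- lapply(pretty[num], function(x) {
    ifelse(is.na(x), NA_character_, formatC(x, digits = 3, format = "g"))
  })
  utils::write.csv(pretty, file.path(out_dir, "results.csv"), row.names = FALSE)
  utils::write.csv(full, file.path(out_dir, "results_full.csv"), row.names = FALSE)
  utils::write.csv(assessment$exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  for (cat in names(assessment$results)) {
    for (metric in c("hi", "ir")) {
      r <- assessment$results[[cat]][[metric]]
      if (!is_computable(r)) next
      stem <- paste0(cat, "_", r$metric)
      utils::write.csv(empirical_cdf(r$draws),
                       file.path(out_dir, paste0("cdf_", stem, ".csv")),
                       row.names = FALSE)
      utils::write.csv(pdf_histogram(r$draws, bins),
                       file.path(out_dir, paste0("pdf_", stem, ".csv")),
                       row.names = FALSE)
    }
  }
  write_run_log(assessment, file.path(out_dir, "run.log"), config)
  invisible(assessment)
}

#' Sensitivity command
#'
#' Replicates the Monte Carlo under independent child seeds and writes
#' `sensitivity.csv` (one row per replicate pair).
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the list of `sensitivity_report`s, invisibly.
#' @export
cmd_sensitivity <- function(config, out_dir = ".") {
  inputs <- load_config_inputs(config)
  model <- fit_risk_model(inputs$sample_set, inputs$tox, inputs$survey,
                          config$constants)
  reports <- run_sensitivity(model, config$iterations, config$replicate_count,
                             config$master_seed, config$sensitivity_tolerance)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sensitivity_table(reports),
                   file.path(out_dir, "sensitivity.csv"), row.names = FALSE)
  invisible(reports)
}

#' Simulate command: write a synthetic dataset as CSV files
#'
#' Emits `samples.csv`, `odor.csv`, `tox_synthetic.csv`, `survey.csv`,
#' `presentations.csv` in the dialects the package readers consume.
#'
#' @param config a [run_config()] with a scenario input.
#' @param out_dir output directory.
#' @return the generated `syn_dataset`, invisibly.
#' @export
cmd_simulate <- function(config, out_dir = ".") {
  if (is.null(config$scenario)) {
    stop("cmd_simulate requires a scenario in the configuration")
  }
  ds <- generate_dataset(config$scenario)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(ds$samples, file.path(out_dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(ds$odor, file.path(out_dir, "odor.csv"), row.names = FALSE)
  utils::write.csv(ds$tox, file.path(out_dir, "tox_synthetic.csv"), row.names = FALSE)
  utils::write.csv(ds$survey, file.path(out_dir, "survey.csv"), row.names = FALSE)
  utils::write.csv(ds$presentations, file.path(out_dir, "presentations.csv"),
                   row.names = FALSE)
  invisible(ds)
}

# Plain-text run log: configuration echo, per-category outcome, exclusions.
write_run_log <- function(assessment, path, config) {
  lines <- c(
    sprintf("olfrisk run log"),
    sprintf("iterations: %d", assessment$iterations),
    sprintf("master_seed: %d", assessment$master_seed),
    sprintf("percentile_used: %g", assessment$percentile_used),
    sprintf("hi_threshold: %g", assessment$hi_threshold),
    sprintf("ir_threshold: %g", assessment$ir_threshold),
    sprintf("constants: n_r=%g it_s=%g k=%g at=%g lt=%g delta_z_max=%g",
            config$constants$n_r, config$constants$it_s,
            config$constants$safety_factor_k, config$constants$at_days_per_year,
            config$constants$lt_years, config$constants$delta_z_max),
    ""
  )
  for (cat in names(assessment$results)) {
    r <- assessment$results[[cat]]
    lines <- c(lines, sprintf(
      "category %s: HI p%g = %.4g (%s); IR %s", cat,
      r$hi$percentile_used, r$hi$quantile_at_percentile,
      if (r$hi$verdict) "acceptable" else "risk flagged",
      if (is_computable(r$ir)) {
        sprintf("p%g = %.4g (%s)", r$ir$percentile_used,
                r$ir$quantile_at_percentile,
                if (r$ir$verdict) "acceptable" else "risk flagged")
      } else r$ir$reason))
  }
  if (nrow(assessment$skipped) > 0) {
    lines <- c(lines, "", "skipped categories:")
    lines <- c(lines, sprintf("  %s: %s", assessment$skipped$category,
                              assessment$skipped$reason))
  }
  if (nrow(assessment$exclusions) > 0) {
    lines <- c(lines, "", "excluded compounds:")
    lines <- c(lines, sprintf("  %s/%s: %s", assessment$exclusions$category,
                              assessment$exclusions$compound_id,
                              assessment$exclusions$reason))
  }
  writeLines(lines, path)
  invisible(path)
}
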