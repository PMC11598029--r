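#' Fit all Monte Carlo input distributions from a laboratory dataset
#'
#' The randomization stage of the method: per category and compound, the
#' per-sample inhalation concentrations Cin = (C_i / C_od) x k of the
#' *detected* values are reduced to a truncated Gaussian spec (absence of a
#' compound in a sample is treated as not-detected, not as zero -- forcing
#' zeros would drag every lower truncation bound to 0 and distort the fitted
#' laws; detection counts are reported instead). The panel survey yields one
#' global spec each for N_PR, F_S and N_Y, reused across categories: the
#' survey describes the laboratory's whole panel, and applying the full
#' exposure to every category is deliberately conservative.
#'
#' @param sample_set a [read_sample_set()] object.
#' @param tox a [load_tox_table()] object.
#' @param survey a [read_panel_survey()] object.
#' @param constants a [lab_constants()] object; `safety_factor_k` scales every
#'   Cin.
#' @return an object of class `risk_model`: list with `categories` (named
#'   list of [category_risk_inputs()]), `exposure` ([exposure_model()]),
#'   `exclusions` (data frame with a `category` column), `detection`
#'   (per category x compound detection counts), `constants`.
#' @export
fit_risk_model <- function(sample_set, tox, survey, constants = lab_constants()) {
  stopifnot(inherits(sample_set, "sample_set"), inherits(tox, "tox_table"),
            inherits(survey, "panel_survey"), inherits(constants, "lab_constants"))
  chem <- merge(sample_set$chemistry, sample_set$odor, by = "sample_id")
  chem$cin <- compute_inhalation_concentration(
    chem$concentration, chem$odor_concentration, constants$safety_factor_k)

  categories <- list()
  exclusions <- list()
  detection <- list()
  for (cat in sort(unique(chem$category))) {
    sub <- chem[chem$category == cat, , drop = FALSE]
    n_char <- length(unique(sub$sample_id))
    if (n_char == 1) {
      warning("category ", sQuote(cat), " has a single characterized sample; ",
              "all its concentration specs are point masses")
    }
    specs <- list()
    for (id in sort(unique(sub$compound_id))) {
      vals <- sub$cin[sub$compound_id == id]
      specs[[id]] <- fit_tg_spec(vals)
      detection[[paste(cat, id, sep = "/")]] <- data.frame(
        category = cat, compound_id = id, n_detected = length(vals),
        n_characterized = n_char, stringsAsFactors = FALSE)
    }
    inputs <- category_risk_inputs(cat, specs, tox)
    categories[[cat]] <- inputs
    if (nrow(inputs$excluded) > 0) {
      exclusions[[cat]] <- cbind(category = cat, inputs$excluded)
    }
  }
  exclusions <- if (length(exclusions) > 0) {
    do.call(rbind, exclusions)
  } else {
    data.frame(category = character(0), compound_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  }
  rownames(exclusions) <- NULL
  detection <- do.call(rbind, detection)
  rownames(detection) <- NULL

  exposure <- exposure_model(
    constants,
    spec_n_pr = fit_tg_spec(survey$presentations$n_presentations),
    spec_f_s = fit_tg_spec(survey$panelists$samples_per_year),
    spec_n_y = fit_tg_spec(survey$panelists$working_years)
  )
  structure(list(categories = categories, exposure = exposure,
                 exclusions = exclusions, detection = detection,
                 constants = constants),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Fitted risk model:", length(x$categories), "categories,",
      nrow(x$detection), "fitted concentration specs,",
      nrow(x$exclusions), "exclusion(s)\n")
  invisible(x)
}

#' Flatten every fitted spec of a risk model to one table
#'
#' @param model a [fit_risk_model()] object.
#' @return data frame: scope (`category/compound` or exposure parameter
#'   name), mu, sigma, lower, upper, n_obs.
#' @export
model_spec_table <- function(model) {
  stopifnot(inherits(model, "risk_model"))
  specs <- list()
  for (cat in names(model$categories)) {
    ci <- model$categories[[cat]]
    for (id in names(ci$cin_specs)) {
      specs[[paste(cat, id, sep = "/")]] <- ci$cin_specs[[id]]
    }
  }
  specs[["n_pr"]] <- model$exposure$spec_n_pr
  specs[["f_s"]] <- model$exposure$spec_f_s
  specs[["n_y"]] <- model$exposure$spec_n_y
  tg_spec_table(specs)
}

#' Run the Monte Carlo risk assessment for every category
#'
#' For each category: an HI distribution always, and an IR distribution or
#' the explicit no-carcinogen marker. A category that cannot be assessed at
#' all (no compound with an OEL) is reported and skipped; the run continues.
#'
#' @param model a [fit_risk_model()] object.
#' @param iterations Monte Carlo iterations (default 1000).
#' @param master_seed integer master seed.
#' @param percentile_used acceptability percentile (default 95).
#' @param hi_threshold,ir_threshold acceptability thresholds (defaults 1 and
#'   1e-5).
#' @return an object of class `risk_assessment`: per-category list of
#'   `hi`/`ir` results, a `skipped` data frame, run metadata, and
#'   `any_flagged` (TRUE when any computed distribution breaches its
#'   threshold).
#' @export
run_assessment <- function(model, iterations = 1000, master_seed,
                           percentile_used = 95, hi_threshold = 1,
                           ir_threshold = 1e-5) {
  stopifnot(inherits(model, "risk_model"))
  results <- list()
  skipped <- list()
  for (cat in names(model$categories)) {
    inputs <- model$categories[[cat]]
    hi <- tryCatch(
      simulate_hi(inputs, iterations, master_seed, percentile_used, hi_threshold),
      error = function(e) e
    )
    if (inherits(hi, "error")) {
      skipped[[cat]] <- data.frame(category = cat,
                                   reason = conditionMessage(hi),
                                   stringsAsFactors = FALSE)
      next
    }
    ir <- simulate_ir(inputs, model$exposure, iterations, master_seed,
                      percentile_used, ir_threshold)
    results[[cat]] <- list(hi = hi, ir = ir)
  }
  skipped <- if (length(skipped) > 0) {
    do.call(rbind, skipped)
  } else {
    data.frame(category = character(0), reason = character(0))
  }
  rownames(skipped) <- NULL
  flagged <- any(vapply(results, function(r) {
    (!r$hi$verdict) || (is_computable(r$ir) && !r$ir$verdict)
  }, logical(1)))
  structure(
    list(results = results, skipped = skipped, exclusions = model$exclusions,
         iterations = iterations, master_seed = master_seed,
         percentile_used = percentile_used, hi_threshold = hi_threshold,
         ir_threshold = ir_threshold, any_flagged = flagged),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat("Probabilistic risk assessment:", length(x$results), "categories at",
      x$iterations, "iterations (seed", x$master_seed, ")\n")
  tab <- assessment_table(x)
  show <- tab[, c("category", "metric", "p95", "verdict")]
  show$p95 <- signif(show$p95, 3)
  print(show, row.names = FALSE)
  if (nrow(x$skipped) > 0) {
    cat("Skipped categories:", paste(x$skipped$category, collapse = ", "), "\n")
  }
  cat(if (x$any_flagged) "At least one scenario breaches its acceptability threshold.\n"
      else sprintf("All computed scenarios acceptable at the %gth percentile.\n",
                   x$percentile_used))
  invisible(x)
}

#' Summary table of an assessment
#'
#' One row per category and metric, mirroring the usual reporting format:
#' mean, SD, percentiles (25/50/75/95), maximum, verdict. Categories without
#' carcinogens get an IR row with NA statistics and the not-computable note.
#'
#' @param x a [run_assessment()] result.
#' @return data frame.
#' @export
assessment_table <- function(x) {
  stopifnot(inherits(x, "risk_assessment"))
  rows <- list()
  for (cat in names(x$results)) {
    for (metric in c("hi", "ir")) {
      r <- x$results[[cat]][[metric]]
      if (is_computable(r)) {
        rows[[paste(cat, metric)]] <- data.frame(
          category = cat, metric = r$metric, mean = r$summary[["mean"]],
          sd = r$summary[["sd"]], p25 = r$summary[["p25"]],
          p50 = r$summary[["p50"]], p75 = r$summary[["p75"]],
          p95 = r$summary[["p95"]], max = r$summary[["max"]],
          verdict = if (r$verdict) "acceptable" else "risk flagged",
          note = "", iterations = r$iterations, seed = r$seed,
          stringsAsFactors = FALSE)
      } else {
        rows[[paste(cat, metric)]] <- data.frame(
          category = cat, metric = r$metric, mean = NA_real_, sd = NA_real_,
          p25 = NA_real_, p50 = NA_real_, p75 = NA_real_, p95 = NA_real_,
          max = NA_real_, verdict = "not computable", note = r$reason,
          iterations = x$iterations, seed = x$master_seed,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sensitivity analysis across all categories of a fitted model
#'
#' Runs [run_replicates()] + [sensitivity_report()] for the HI of every
#' category and for the IR of every category holding carcinogens.
#'
#' @param model a [fit_risk_model()] object.
#' @param iterations iterations per replicate (default 1000).
#' @param replicate_count replicates (default 5).
#' @param master_seed integer master seed.
#' @param tolerance maximum acceptable pairwise CDF distance (default 0.05).
#' @return list of `sensitivity_report` objects, named `category/metric`.
#' @export
run_sensitivity <- function(model, iterations = 1000, replicate_count = 5,
                            master_seed, tolerance = 0.05) {
  stopifnot(inherits(model, "risk_model"))
  reports <- list()
  for (cat in names(model$categories)) {
    inputs <- model$categories[[cat]]
    hi_reps <- tryCatch(
      run_replicates(inputs, metric = "HI", iterations = iterations,
                     replicate_count = replicate_count,
                     master_seed = child_seed(master_seed, paste0("sens:hi:", cat))),
      error = function(e) NULL
    )
    if (!is.null(hi_reps)) {
      reports[[paste(cat, "HI", sep = "/")]] <- sensitivity_report(hi_reps, tolerance)
    }
    ir_reps <- run_replicates(inputs, model$exposure, metric = "IR",
                              iterations = iterations,
                              replicate_count = replicate_count,
                              master_seed = child_seed(master_seed, paste0("sens:ir:", cat)))
    if (all(vapply(ir_reps, is_computable, logical(1)))) {
      reports[[paste(cat, "IR", sep = "/")]] <- sensitivity_report(ir_reps, tolerance)
    }
  }
  reports
}

#' Flatten sensitivity reports to a table
#'
#' @param reports result of [run_sensitivity()].
#' @return data frame: metric, category, replicate pair, distance, tolerance,
#'   stable.
#' @export
sensitivity_table <- function(reports) {
  rows <- list()
  for (nm in names(reports)) {
    rep <- reports[[nm]]
    k <- rep$replicate_count
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        rows[[paste(nm, i, j)]] <- data.frame(
          metric = rep$metric, category = rep$category,
          replicate_a = i, replicate_b = j,
          distance = rep$pairwise_sup_distances[i, j],
          tolerance = rep$tolerance, stable = rep$stable,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
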