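#' Synthetic compound specification
#'
#' Generating law for one compound inside a category: concentrations are
#' log-normal (right-skewed, concentrated toward low values -- the shape
#' routinely observed for trace compounds in odor samples), thinned by a
#' per-sample detection probability. The toxicological reference values
#' carried here are written into the synthetic tox table.
#'
#' @param compound_id opaque compound key.
#' @param meanlog,sdlog log-scale location and spread of the concentration
#'   law, concentration in ug/m3.
#' @param detect_prob probability the compound is reported in a characterized
#'   sample (in (0, 1]).
#' @param oel_value_mg OEL value, mg/m3 (written to the tox table).
#' @param oel_kind `"short_term_15min"` or `"twa_8h"`.
#' @param iur inhalation unit risk per (ug/m3), or `NA` for a non-carcinogen.
#' @param conc_cap truncation guard: generated concentrations are capped at
#'   this value (ug/m3; default `Inf`).
#' @return an object of class `syn_compound`.
#' @export
syn_compound <- function(compound_id, meanlog, sdlog, detect_prob = 1,
                         oel_value_mg, oel_kind = "twa_8h", iur = NA_real_,
                         conc_cap = Inf) {
  stopifnot(detect_prob > 0, detect_prob <= 1, sdlog >= 0, oel_value_mg > 0,
            oel_kind %in% c("short_term_15min", "twa_8h"))
  structure(list(compound_id = compound_id, meanlog = meanlog, sdlog = sdlog,
                 detect_prob = detect_prob, oel_value_mg = oel_value_mg,
                 oel_kind = oel_kind, iur = iur, conc_cap = conc_cap),
            class = "syn_compound")
}

#' Synthetic category specification
#'
#' @param name category label.
#' @param n_samples olfactometric samples in the category (>= 1).
#' @param chem_fraction share of samples that are chemically characterized
#'   (in (0, 1]); exactly `round(chem_fraction * n_samples)` samples carry
#'   chemistry, the rest have an odor concentration only.
#' @param compounds list of [syn_compound()] objects.
#' @param odor_meanlog,odor_sdlog log-scale law of the odor concentration
#'   (ou_E/m3) across samples.
#' @return an object of class `syn_category`.
#' @export
syn_category <- function(name, n_samples, chem_fraction, compounds,
                         odor_meanlog, odor_sdlog) {
  stopifnot(n_samples >= 1, chem_fraction > 0, chem_fraction <= 1,
            length(compounds) >= 1, odor_sdlog >= 0)
  if (!all(vapply(compounds, inherits, logical(1), "syn_compound"))) {
    stop("compounds must be a list of syn_compound objects")
  }
  structure(list(name = name, n_samples = as.integer(n_samples),
                 chem_fraction = chem_fraction, compounds = compounds,
                 odor_meanlog = odor_meanlog, odor_sdlog = odor_sdlog),
            class = "syn_category")
}

#' Synthetic panel specification
#'
#' Generating truncated Gaussian laws for the panel survey: working years
#' (N_Y), samples analyzed per year (F_S) and presentations per sample (N_PR).
#'
#' @param n_panelists number of panelists (>= 1).
#' @param spec_n_y,spec_f_s,spec_n_pr generating `tg_spec`s (lower bound > 0).
#' @param analyses_per_panelist recorded N_PR observations per panelist
#'   (default 20).
#' @return an object of class `syn_panel`.
#' @export
syn_panel <- function(n_panelists, spec_n_y, spec_f_s, spec_n_pr,
                      analyses_per_panelist = 20) {
  stopifnot(n_panelists >= 1, analyses_per_panelist >= 1,
            inherits(spec_n_y, "tg_spec"), inherits(spec_f_s, "tg_spec"),
            inherits(spec_n_pr, "tg_spec"))
  for (s in list(spec_n_y, spec_f_s, spec_n_pr)) {
    if (s$lower <= 0) stop("panel generating specs must have lower > 0")
  }
  structure(list(n_panelists = as.integer(n_panelists), spec_n_y = spec_n_y,
                 spec_f_s = spec_f_s, spec_n_pr = spec_n_pr,
                 analyses_per_panelist = as.integer(analyses_per_panelist)),
            class = "syn_panel")
}

#' Synthetic laboratory scenario
#'
#' @param categories list of [syn_category()] objects (>= 1).
#' @param panel a [syn_panel()].
#' @param master_seed integer; the dataset is a pure function of the scenario
#'   and this seed.
#' @return an object of class `syn_scenario`.
#' @export
syn_scenario <- function(categories, panel, master_seed) {
  stopifnot(length(categories) >= 1, inherits(panel, "syn_panel"))
  if (!all(vapply(categories, inherits, logical(1), "syn_category"))) {
    stop("categories must be a list of syn_category objects")
  }
  nm <- vapply(categories, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate category name(s)")
  names(categories) <- nm
  structure(list(categories = categories, panel = panel,
                 master_seed = as.integer(master_seed)),
            class = "syn_scenario")
}

#' Generate a synthetic laboratory dataset
#'
#' Emulates one annual survey of an olfactometric laboratory: every sample
#' gets an odor concentration; exactly `round(chem_fraction * n_samples)`
#' samples per category are chemically characterized (the partial-
#' characterization design of real surveys, where chemical analysis covers
#' about a quarter of the olfactometric samples); detected concentrations are
#' log-normal with per-compound detection thinning; the panel survey draws
#' N_Y, F_S and per-analysis N_PR counts from the generating truncated
#' Gaussian laws. The output tables use the same CSV dialects the package
#' readers consume, so generated data exercises the real input path. All
#' values, including which samples are characterized, are a deterministic
#' function of `scenario$master_seed`.
#'
#' @param scenario a [syn_scenario()].
#' @return list of class `syn_dataset`: data frames `samples` (long-format
#'   chemistry, unit ug/m3), `odor`, `tox` (synthetic toxicology table),
#'   `survey`, `presentations`, `characterized` (which samples carry
#'   chemistry; a characterized sample may still report no compound when
#'   detection thinning removes them all), plus `truth` (the generating
#'   scenario echoed).
#' @export
generate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "syn_scenario"))
  seed0 <- scenario$master_seed
  samples <- list()
  odor <- list()
  characterized <- list()
  for (cat in scenario$categories) {
    ids <- sprintf("%s_%04d", cat$name, seq_len(cat$n_samples))
    c_od <- with_seed(child_seed(seed0, paste0("gen:odor:", cat$name)),
                      stats::rlnorm(cat$n_samples, cat$odor_meanlog, cat$odor_sdlog))
    odor[[cat$name]] <- data.frame(sample_id = ids, odor_concentration = c_od,
                                   stringsAsFactors = FALSE)
    n_chem <- round(cat$chem_fraction * cat$n_samples)
    chem_idx <- with_seed(child_seed(seed0, paste0("gen:chemsel:", cat$name)),
                          sort(sample.int(cat$n_samples, n_chem)))
    characterized[[cat$name]] <- data.frame(
      category = cat$name, sample_id = ids[chem_idx], stringsAsFactors = FALSE)
    rows <- list()
    for (cmp in cat$compounds) {
      stream <- child_seed(seed0, paste0("gen:conc:", cat$name, ":", cmp$compound_id))
      vals <- with_seed(stream, {
        detected <- stats::runif(n_chem) <= cmp$detect_prob
        conc <- stats::rlnorm(n_chem, cmp$meanlog, cmp$sdlog)
        list(detected = detected, conc = pmin(conc, cmp$conc_cap))
      })
      if (any(vals$detected)) {
        rows[[cmp$compound_id]] <- data.frame(
          sample_id = ids[chem_idx][vals$detected],
          category = cat$name,
          compound_id = cmp$compound_id,
          concentration = vals$conc[vals$detected],
          unit = "ug/m3",
          stringsAsFactors = FALSE
        )
      }
    }
    samples[[cat$name]] <- do.call(rbind, rows)
  }
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL
  odor <- do.call(rbind, odor)
  rownames(odor) <- NULL
  characterized <- do.call(rbind, characterized)
  rownames(characterized) <- NULL

  # synthetic toxicology table (values are plausible placeholders, not a
  # regulatory reference)
  cmp_all <- unlist(lapply(scenario$categories, `[[`, "compounds"),
                    recursive = FALSE)
  cmp_ids <- vapply(cmp_all, `[[`, character(1), "compound_id")
  cmp_all <- cmp_all[!duplicated(cmp_ids)]
  tox <- do.call(rbind, lapply(cmp_all, function(cmp) {
    data.frame(compound_id = cmp$compound_id, oel_value = cmp$oel_value_mg,
               oel_unit = "mg/m3", oel_kind = cmp$oel_kind,
               iur = cmp$iur, iur_unit = "per_ug_m3",
               source_note = "synthetic placeholder", stringsAsFactors = FALSE)
  }))
  rownames(tox) <- NULL

  pan <- scenario$panel
  pids <- sprintf("panelist_%02d", seq_len(pan$n_panelists))
  n_y <- tg_sample(pan$spec_n_y, pan$n_panelists, child_seed(seed0, "gen:n_y"))
  f_s <- tg_sample(pan$spec_f_s, pan$n_panelists, child_seed(seed0, "gen:f_s"))
  survey <- data.frame(panelist_id = pids, working_years = n_y,
                       samples_per_year = f_s, stringsAsFactors = FALSE)
  presentations <- do.call(rbind, lapply(seq_along(pids), function(i) {
    npr <- tg_sample_integer(pan$spec_n_pr, pan$analyses_per_panelist,
                             child_seed(seed0, paste0("gen:n_pr:", pids[i])))
    data.frame(panelist_id = pids[i],
               sample_id = sprintf("analysis_%02d_%03d", i,
                                   seq_len(pan$analyses_per_panelist)),
               n_presentations = npr, stringsAsFactors = FALSE)
  }))
  rownames(presentations) <- NULL

  structure(list(samples = samples, odor = odor, tox = tox, survey = survey,
                 presentations = presentations, characterized = characterized,
                 truth = scenario),
            class = "syn_dataset")
}

#' @export
print.syn_dataset <- function(x, ...) {
  cat("Synthetic olfactometry dataset:", nrow(x$odor), "samples in",
      length(x$truth$categories), "categories;",
      nrow(x$characterized), "chemically characterized;",
      nrow(x$survey), "panelists\n")
  invisible(x)
}

#' Closed-form risk reference for a single-compound category
#'
#' For a category holding exactly one assessed compound, the Monte Carlo HI is
#' a monotone transform of one truncated Gaussian, so its quantiles are
#' available in closed form: HI quantile = Cin quantile / OEL. With a
#' *degenerate* exposure model (all three exposure specs with sigma 0) the
#' lifetime exposure fraction is a constant and the IR quantiles follow the
#' same way: IR quantile = Cin quantile x IUR x fraction. These references are
#' what the Monte Carlo pipeline is validated against.
#'
#' @param inputs a [category_risk_inputs()] with exactly one resolved
#'   compound.
#' @param exposure an [exposure_model()] with degenerate (sigma 0) specs;
#'   only needed for the IR reference. N_PR is rounded to the nearest integer
#'   as in the integer sampler.
#' @param hi_percentile percentile of the HI reference (default 95).
#' @param ir_percentile percentile of the IR reference (default 50).
#' @return list with `hi` (reference HI quantile) and `ir` (reference IR
#'   quantile, or a `risk_not_computable` marker when the compound has no
#'   IUR).
#' @export
analytic_reference_risk <- function(inputs, exposure = NULL,
                                    hi_percentile = 95, ir_percentile = 50) {
  stopifnot(inherits(inputs, "category_risk_inputs"))
  if (length(inputs$cin_specs) != 1) {
    stop("closed-form reference requires exactly one compound; got ",
         length(inputs$cin_specs))
  }
  id <- names(inputs$cin_specs)
  spec <- inputs$cin_specs[[id]]
  prof <- inputs$tox[[id]]
  if (is.na(prof$oel_value)) stop("compound ", id, " has no active OEL")
  hi <- tg_quantile(spec, hi_percentile / 100) / prof$oel_value

  if (is.na(prof$iur)) {
    ir <- structure(
      list(metric = "IR", category = inputs$category,
           reason = "not computable: no carcinogenic compound (no IUR) in this category"),
      class = "risk_not_computable"
    )
  } else {
    if (is.null(exposure)) stop("an exposure_model is required for the IR reference")
    for (nm in c("spec_n_pr", "spec_f_s", "spec_n_y")) {
      if (exposure[[nm]]$sigma != 0) {
        stop("closed-form IR reference requires degenerate exposure specs (sigma 0); ",
             nm, " has sigma ", exposure[[nm]]$sigma)
      }
    }
    cst <- exposure$constants
    clamp <- function(s) pmin(pmax(s$mu, s$lower), s$upper)
    n_pr <- max(min(round(clamp(exposure$spec_n_pr)), floor(exposure$spec_n_pr$upper)),
                max(ceiling(exposure$spec_n_pr$lower), 1))
    fraction <- lifetime_exposure_fraction(
      clamp(exposure$spec_n_y), clamp(exposure$spec_f_s), n_pr,
      cst$n_r, cst$it_s, cst$at_days_per_year, cst$lt_years)
    ir <- tg_quantile(spec, ir_percentile / 100) * prof$iur * fraction
  }
  list(hi = hi, ir = ir)
}

#' Default synthetic scenario
#'
#' A plausible annual survey of an olfactometric laboratory: 13 industrial
#' sample categories totalling 1035 olfactometric samples, 25% of which are
#' chemically characterized; a 15-member panel with widely dispersed working
#' years and analysis frequencies. Compound panels and all toxicological
#' values are synthetic placeholders chosen for realism of scale, not a
#' regulatory reference; two categories (`wwtp`, `biofuel`) deliberately
#' contain no carcinogen, so their inhalation risk is not computable.
#'
#' @param master_seed integer seed (default 101).
#' @return a [syn_scenario()].
#' @export
default_scenario <- function(master_seed = 101) {
  lib <- list(
    toluene = syn_compound("toluene", log(1500), 1.0, 0.9, 75, "twa_8h"),
    xylene = syn_compound("xylene", log(900), 1.0, 0.8, 651, "short_term_15min"),
    benzene = syn_compound("benzene", log(400), 1.1, 0.7, 1.6, "twa_8h",
                           iur = 7.8e-6),
    ethylbenzene = syn_compound("ethylbenzene", log(600), 1.0, 0.7, 435,
                                "twa_8h", iur = 2.5e-6),
    formaldehyde = syn_compound("formaldehyde", log(120), 0.9, 0.6, 0.37,
                                "short_term_15min", iur = 1.3e-5),
    acetaldehyde = syn_compound("acetaldehyde", log(200), 0.9, 0.6, 45,
                                "short_term_15min", iur = 2.2e-6),
    hydrogen_sulfide = syn_compound("hydrogen_sulfide", log(800), 1.2, 0.9, 7,
                                    "short_term_15min"),
    ammonia = syn_compound("ammonia", log(1200), 1.0, 0.9, 24,
                           "short_term_15min"),
    limonene = syn_compound("limonene", log(300), 1.1, 0.8, 150, "twa_8h"),
    alpha_pinene = syn_compound("alpha_pinene", log(250), 1.0, 0.7, 112,
                                "twa_8h"),
    butanol = syn_compound("butanol", log(350), 0.9, 0.7, 152, "twa_8h"),
    dimethyl_sulfide = syn_compound("dimethyl_sulfide", log(500), 1.1, 0.8,
                                    25, "twa_8h"),
    styrene = syn_compound("styrene", log(450), 1.0, 0.7, 85, "twa_8h")
  )
  cats <- list(
    syn_category("refinery", 120, 0.25,
                 lib[c("toluene", "xylene", "benzene", "hydrogen_sulfide")],
                 log(600), 0.9),
    syn_category("bitumen", 85, 0.25,
                 lib[c("toluene", "xylene", "styrene", "benzene", "hydrogen_sulfide")],
                 log(500), 0.9),
    syn_category("petrochemical_cracking", 90, 0.25,
                 lib[c("benzene", "toluene", "ethylbenzene", "xylene", "styrene")],
                 log(450), 1.0),
    syn_category("petrochemical_polymers", 80, 0.25,
                 lib[c("styrene", "ethylbenzene", "toluene", "acetaldehyde")],
                 log(400), 1.0),
    syn_category("hydrocarbon_tanks", 75, 0.25,
                 lib[c("toluene", "xylene", "benzene")],
                 log(700), 0.9),
    syn_category("wwtp", 110, 0.25,
                 lib[c("hydrogen_sulfide", "ammonia", "dimethyl_sulfide", "limonene")],
                 log(800), 1.0),
    syn_category("biofuel", 60, 0.25,
                 lib[c("ammonia", "butanol", "dimethyl_sulfide")],
                 log(650), 0.9),
    syn_category("composting", 95, 0.25,
                 lib[c("ammonia", "limonene", "alpha_pinene", "acetaldehyde")],
                 log(900), 1.0),
    syn_category("landfill", 90, 0.25,
                 lib[c("hydrogen_sulfide", "benzene", "toluene", "limonene")],
                 log(750), 1.0),
    syn_category("foundry", 55, 0.25,
                 lib[c("formaldehyde", "toluene", "xylene")],
                 log(350), 0.9),
    syn_category("food_industry", 65, 0.25,
                 lib[c("acetaldehyde", "butanol", "limonene")],
                 log(550), 0.9),
    syn_category("biomass", 70, 0.25,
                 lib[c("limonene", "alpha_pinene", "formaldehyde", "butanol")],
                 log(500), 1.0),
    syn_category("tannery", 40, 0.25,
                 lib[c("hydrogen_sulfide", "ammonia", "formaldehyde")],
                 log(600), 0.9)
  )
  panel <- syn_panel(
    n_panelists = 15,
    spec_n_y = tg_spec(8, 6, 1, 25),
    spec_f_s = tg_spec(250, 180, 20, 700),
    spec_n_pr = tg_spec(9, 3, 4, 18),
    analyses_per_panelist = 20
  )
  syn_scenario(cats, panel, master_seed)
}
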