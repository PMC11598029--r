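#' Olfactometer and laboratory constants
#'
#' Fixed quantities of the exposure model. Within one laboratory the number of
#' rounds per sample (`n_r`) and the presentation time are set on the
#' olfactometer and do not vary between analyses, so they are constants rather
#' than randomized inputs. The inhalation time `it_s` is conservatively
#' approximated by the presentation time (the panelist is assumed to inhale
#' for the whole presentation). The averaging time (365 days/year) and
#' lifetime (70 years) follow the U.S. EPA convention for chronic risk.
#'
#' @param n_r rounds per sample (default 3, the minimum panel round count).
#' @param it_s inhalation time per presentation, seconds (default 3; typical
#'   presentation times are 2-3 s).
#' @param safety_factor_k conservative multiplier applied to the
#'   threshold-level concentration (default 10 = delta_z_max x 2; see
#'   [compute_safety_factor()]).
#' @param at_days_per_year averaging time, days/year (default 365).
#' @param lt_years lifetime, years (default 70).
#' @param delta_z_max maximum admissible panel screening deviation (default 5).
#' @return an object of class `lab_constants`.
#' @export
lab_constants <- function(n_r = 3, it_s = 3, safety_factor_k = 10,
                          at_days_per_year = 365, lt_years = 70,
                          delta_z_max = 5) {
  vals <- c(n_r = n_r, it_s = it_s, safety_factor_k = safety_factor_k,
            at_days_per_year = at_days_per_year, lt_years = lt_years,
            delta_z_max = delta_z_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all laboratory constants must be strictly positive")
  }
  if (n_r != round(n_r) || n_r < 1) stop("n_r must be a positive integer")
  structure(as.list(vals), class = "lab_constants")
}

#' @export
print.lab_constants <- function(x, ...) {
  cat(sprintf(
    "Laboratory constants: N_R = %g rounds, IT = %g s, k = %g, AT = %g d/yr, LT = %g yr, deltaZ_max = %g\n",
    x$n_r, x$it_s, x$safety_factor_k, x$at_days_per_year, x$lt_years,
    x$delta_z_max))
  invisible(x)
}

#' Read per-sample chemistry and odor concentrations
#'
#' `samples` is long-format chemistry: one row per (sample, compound) with
#' columns `sample_id`, `category`, `compound_id`, `concentration`, `unit`.
#' `odor` carries one row per olfactometric sample: `sample_id`,
#' `odor_concentration` (ou_E/m3). Only a fraction of olfactometric samples is
#' normally chemically characterized, so `odor` may (and usually does) contain
#' sample ids absent from `samples`; the reverse is an error, because a
#' characterized sample without an odor concentration cannot be converted to
#' an inhalation concentration. Concentrations are canonicalized to ug/m3 at
#' this single point.
#'
#' @param samples,odor data frames or CSV paths.
#' @return an object of class `sample_set`: list with `chemistry` (canonical
#'   ug/m3), `odor`, and `categories`.
#' @export
read_sample_set <- function(samples, odor) {
  if (is.character(samples)) samples <- utils::read.csv(samples, stringsAsFactors = FALSE)
  if (is.character(odor)) odor <- utils::read.csv(odor, stringsAsFactors = FALSE)
  need_s <- c("sample_id", "category", "compound_id", "concentration", "unit")
  need_o <- c("sample_id", "odor_concentration")
  if (length(setdiff(need_s, names(samples))) > 0) {
    stop("samples table is missing column(s): ",
         paste(setdiff(need_s, names(samples)), collapse = ", "))
  }
  if (length(setdiff(need_o, names(odor))) > 0) {
    stop("odor table is missing column(s): ",
         paste(setdiff(need_o, names(odor)), collapse = ", "))
  }
  if (anyDuplicated(odor$sample_id)) {
    stop("duplicate sample_id in odor table: ",
         paste(unique(odor$sample_id[duplicated(odor$sample_id)]), collapse = ", "))
  }
  if (any(!is.finite(odor$odor_concentration) | odor$odor_concentration <= 0)) {
    stop("odor_concentration must be finite and > 0 for every sample")
  }
  orphan <- setdiff(samples$sample_id, odor$sample_id)
  if (length(orphan) > 0) {
    stop("characterized sample(s) without an odor concentration: ",
         paste(utils::head(orphan, 5), collapse = ", "))
  }
  chemistry <- data.frame(
    sample_id = as.character(samples$sample_id),
    category = as.character(samples$category),
    compound_id = as.character(samples$compound_id),
    concentration = canonicalize_concentration(samples$concentration, samples$unit),
    stringsAsFactors = FALSE
  )
  odor <- data.frame(sample_id = as.character(odor$sample_id),
                     odor_concentration = odor$odor_concentration,
                     stringsAsFactors = FALSE)
  cats <- sort(unique(chemistry$category))
  structure(list(chemistry = chemistry, odor = odor, categories = cats),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("Olfactometric sample set:", nrow(x$odor), "sample(s),",
      length(unique(x$chemistry$sample_id)), "chemically characterized;",
      length(unique(x$chemistry$compound_id)), "distinct compound(s) across",
      length(x$categories), "category/ies\n")
  invisible(x)
}

#' Read the panelist exposure survey
#'
#' `survey` holds one row per panelist: `panelist_id`, `working_years` (N_Y),
#' `samples_per_year` (F_S). `presentations` holds one row per recorded
#' analysis: `panelist_id`, `sample_id`, `n_presentations` (N_PR, a positive
#' integer count).
#'
#' @param survey,presentations data frames or CSV paths.
#' @return an object of class `panel_survey`: list with `panelists` and
#'   `presentations` data frames.
#' @export
read_panel_survey <- function(survey, presentations) {
  if (is.character(survey)) survey <- utils::read.csv(survey, stringsAsFactors = FALSE)
  if (is.character(presentations)) {
    presentations <- utils::read.csv(presentations, stringsAsFactors = FALSE)
  }
  need <- c("panelist_id", "working_years", "samples_per_year")
  if (length(setdiff(need, names(survey))) > 0) {
    stop("survey table is missing column(s): ",
         paste(setdiff(need, names(survey)), collapse = ", "))
  }
  need_p <- c("panelist_id", "n_presentations")
  if (length(setdiff(need_p, names(presentations))) > 0) {
    stop("presentations table is missing column(s): ",
         paste(setdiff(need_p, names(presentations)), collapse = ", "))
  }
  if (any(survey$working_years <= 0) || any(survey$samples_per_year <= 0)) {
    stop("working_years and samples_per_year must be > 0")
  }
  if (any(presentations$n_presentations < 1) ||
      any(presentations$n_presentations != round(presentations$n_presentations))) {
    stop("n_presentations must be positive integers")
  }
  structure(list(panelists = survey, presentations = presentations),
            class = "panel_survey")
}

#' @export
print.panel_survey <- function(x, ...) {
  cat("Panel survey:", nrow(x$panelists), "panelist(s),",
      nrow(x$presentations), "recorded analyses (N_PR observations)\n")
  invisible(x)
}
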