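#' Hazard quotient of a single compound
#'
#' HQ_i = Cin_i / OEL_i, both in ug/m3.
#'
#' @param cin inhalation concentration, ug/m3 (>= 0; vectorized).
#' @param oel occupational exposure limit, ug/m3 (> 0).
#' @return hazard quotient(s).
#' @export
hazard_quotient <- function(cin, oel) {
  if (any(!is.finite(oel)) || any(oel <= 0)) stop("OEL must be > 0")
  if (any(cin < 0)) stop("cin must be >= 0")
  cin / oel
}

#' Hazard index of a mixture
#'
#' HI = sum of the hazard quotients of all assessed compounds; an empty
#' mixture has HI = 0.
#'
#' @param hqs numeric vector of hazard quotients (>= 0).
#' @return scalar HI.
#' @export
hazard_index <- function(hqs) {
  if (any(hqs < 0)) stop("hazard quotients must be >= 0")
  sum(hqs)
}

#' Lifetime exposure fraction of a panelist
#'
#' The fraction of a 70-year lifetime spent inhaling odor samples:
#' `f = (n_y * f_s * n_pr * n_r * it_s/86400) / (at * lt)`. The numerator is
#' total inhalation time in days (working years x samples/year x presentations
#' per sample x rounds x seconds per presentation); the denominator is the
#' regulatory averaging window (365 days/year x 70 years). Multiplying a
#' concentration by this fraction gives the chronic daily intake (CDI).
#'
#' @param n_y working years (N_Y).
#' @param f_s samples analyzed per year (F_S).
#' @param n_pr presentations per sample (N_PR).
#' @param n_r rounds per sample (N_R).
#' @param it_s inhalation time per presentation, seconds.
#' @param at averaging time, days/year (default 365).
#' @param lt lifetime, years (default 70).
#' @return dimensionless fraction (vectorized over the randomized arguments).
#' @export
lifetime_exposure_fraction <- function(n_y, f_s, n_pr, n_r, it_s,
                                       at = 365, lt = 70) {
  args <- list(n_y, f_s, n_pr, n_r, it_s, at, lt)
  if (any(vapply(args, function(a) any(!is.finite(a)) || any(a <= 0), logical(1)))) {
    stop("all exposure-fraction inputs must be finite and > 0")
  }
  (n_y * f_s * n_pr * n_r * (it_s / 86400)) / (at * lt)
}

#' Inhalation (carcinogenic) risk of a single compound
#'
#' IR_i = CDI x IUR with CDI = Cin_i x lifetime exposure fraction. An IUR of
#' zero (or a non-carcinogen) contributes zero.
#'
#' @param cin inhalation concentration, ug/m3 (>= 0).
#' @param iur inhalation unit risk, per (ug/m3) (>= 0).
#' @param fraction dimensionless lifetime exposure fraction (>= 0).
#' @return excess lifetime cancer risk (vectorized).
#' @export
inhalation_risk <- function(cin, iur, fraction) {
  if (any(cin < 0) || any(iur < 0) || any(fraction < 0)) {
    stop("cin, iur and fraction must be >= 0")
  }
  cin * fraction * iur
}

#' Exposure model: constants plus randomized panel parameters
#'
#' @param constants a [lab_constants()] object.
#' @param spec_n_pr `tg_spec` for presentations per sample (N_PR).
#' @param spec_f_s `tg_spec` for samples analyzed per year (F_S).
#' @param spec_n_y `tg_spec` for working years (N_Y).
#' @return an object of class `exposure_model`.
#' @export
exposure_model <- function(constants, spec_n_pr, spec_f_s, spec_n_y) {
  stopifnot(inherits(constants, "lab_constants"),
            inherits(spec_n_pr, "tg_spec"),
            inherits(spec_f_s, "tg_spec"),
            inherits(spec_n_y, "tg_spec"))
  for (nm in c("spec_n_pr", "spec_f_s", "spec_n_y")) {
    s <- get(nm)
    if (s$lower <= 0) stop(nm, ": truncation lower bound must be > 0")
  }
  structure(list(constants = constants, spec_n_pr = spec_n_pr,
                 spec_f_s = spec_f_s, spec_n_y = spec_n_y),
            class = "exposure_model")
}

#' @export
print.exposure_model <- function(x, ...) {
  cat("Exposure model\n")
  print(x$constants)
  cat("  N_PR: "); print(x$spec_n_pr)
  cat("  F_S : "); print(x$spec_f_s)
  cat("  N_Y : "); print(x$spec_n_y)
  invisible(x)
}

#' Monte Carlo risk inputs for one sample category
#'
#' Pairs the fitted inhalation-concentration specs of a category with the
#' toxicology table, resolving every compound to a usable profile or an
#' explicit exclusion.
#'
#' @param category category label.
#' @param cin_specs named list of `tg_spec` (ug/m3), one per detected compound.
#' @param tox a `tox_table`.
#' @return an object of class `category_risk_inputs`: list with `category`,
#'   `cin_specs` (restricted to resolved compounds), `tox` (resolved
#'   profiles), `excluded` (data frame).
#' @export
category_risk_inputs <- function(category, cin_specs, tox) {
  stopifnot(is.character(category), length(category) == 1, is.list(cin_specs))
  if (is.null(names(cin_specs)) || any(!nzchar(names(cin_specs)))) {
    stop("cin_specs must be a named list keyed by compound_id")
  }
  res <- resolve_compounds(tox, names(cin_specs))
  structure(
    list(category = category,
         cin_specs = cin_specs[names(res$resolved)],
         tox = res$resolved,
         excluded = res$excluded),
    class = "category_risk_inputs"
  )
}

#' @export
print.category_risk_inputs <- function(x, ...) {
  cat("Risk inputs for category", sQuote(x$category), "-",
      length(x$cin_specs), "compound(s);", nrow(x$excluded), "excluded\n")
  invisible(x)
}

#' Summary statistics and acceptability verdict for risk draws
#'
#' Empirical quantiles use linear interpolation between order statistics
#' (R quantile type 7); the convention is recorded in the result. The verdict
#' is strict: the scenario is acceptable iff the quantile at
#' `percentile_used` lies strictly below `threshold` (a risk equal to the
#' threshold is unacceptable).
#'
#' @param draws numeric vector of Monte Carlo risk draws (>= 1 value).
#' @param percentile_used acceptability percentile (default 95).
#' @param threshold acceptability threshold (HI: 1; IR: 1e-5).
#' @param metric `"HI"` or `"IR"`.
#' @param category category label.
#' @param seed seed recorded in the result (bookkeeping only).
#' @return an object of class `risk_distribution`.
#' @export
summarize_draws <- function(draws, percentile_used = 95, threshold,
                            metric = c("HI", "IR"), category = "",
                            seed = NA_integer_) {
  metric <- match.arg(metric)
  if (length(draws) < 1) stop("at least one draw is required")
  if (any(draws < 0)) stop("risk draws must be >= 0")
  probs <- c(0.25, 0.50, 0.75, 0.95)
  qs <- stats::quantile(draws, probs, names = FALSE, type = 7)
  q_used <- stats::quantile(draws, percentile_used / 100, names = FALSE, type = 7)
  summary <- c(mean = mean(draws), sd = stats::sd(draws),
               p25 = qs[1], p50 = qs[2], p75 = qs[3], p95 = qs[4],
               max = max(draws))
  structure(
    list(metric = metric, category = category, draws = draws,
         summary = summary, verdict = unname(q_used < threshold),
         threshold = threshold, percentile_used = percentile_used,
         quantile_at_percentile = q_used,
         iterations = length(draws), seed = seed,
         quantile_convention = "linear interpolation between order statistics (type 7)"),
    class = "risk_distribution"
  )
}

#' @export
print.risk_distribution <- function(x, ...) {
  cat(sprintf("%s distribution for category %s (%d iterations)\n",
              x$metric, sQuote(x$category), x$iterations))
  print(signif(x$summary, 3))
  cat(sprintf("  p%g = %.3g vs threshold %.3g -> %s\n", x$percentile_used,
              x$quantile_at_percentile, x$threshold,
              if (x$verdict) "ACCEPTABLE" else "RISK FLAGGED"))
  invisible(x)
}

#' Monte Carlo hazard index distribution for one category
#'
#' Per iteration, each compound's inhalation concentration is drawn
#' independently from its truncated Gaussian spec and divided by its active
#' OEL; the hazard quotients are summed into one HI draw. The HI model
#' involves no exposure-duration parameters (it compares concentration to a
#' concentration limit), so nothing else is randomized. Each compound consumes
#' its own child seed derived from `seed`, so adding or removing a compound
#' leaves the other streams untouched; the HI and IR simulations use disjoint
#' stream names.
#'
#' @param inputs a [category_risk_inputs()] object.
#' @param iterations number of Monte Carlo draws (default 1000).
#' @param seed master seed for this simulation.
#' @param percentile_used,threshold acceptability rule (defaults 95 and 1).
#' @return a `risk_distribution` with `metric = "HI"`.
#' @export
simulate_hi <- function(inputs, iterations = 1000, seed,
                        percentile_used = 95, threshold = 1) {
  stopifnot(inherits(inputs, "category_risk_inputs"), iterations >= 1)
  with_oel <- names(inputs$tox)[vapply(inputs$tox, function(p) !is.na(p$oel_value),
                                       logical(1))]
  if (length(with_oel) == 0) {
    stop("no compound with an active OEL in category ", sQuote(inputs$category),
         "; excluded: ",
         paste(c(names(inputs$tox), inputs$excluded$compound_id), collapse = ", "))
  }
  draws <- numeric(iterations)
  for (id in sort(with_oel)) {
    cs <- child_seed(seed, paste0("hi:cin:", inputs$category, ":", id))
    cin <- tg_sample(inputs$cin_specs[[id]], iterations, cs)
    draws <- draws + hazard_quotient(cin, inputs$tox[[id]]$oel_value)
  }
  summarize_draws(draws, percentile_used, threshold, "HI", inputs$category, seed)
}

#' Monte Carlo inhalation-risk distribution for one category
#'
#' Per iteration: one inhalation-concentration draw per carcinogen (compounds
#' with an IUR), one draw each of N_PR, F_S and N_Y from the exposure model,
#' and fixed N_R, IT, AT, LT. The per-compound risks Cin_i x IUR_i are summed
#' within the iteration and multiplied by the lifetime exposure fraction. All
#' presentations are assumed to occur at the full (confirmation-level)
#' concentration -- no discount for the ascending dilution ladder -- which is
#' deliberately conservative. Categories without any carcinogen return an
#' explicit not-computable marker rather than a distribution.
#'
#' @param inputs a [category_risk_inputs()] object.
#' @param exposure an [exposure_model()].
#' @param iterations number of Monte Carlo draws (default 1000).
#' @param seed master seed for this simulation.
#' @param percentile_used,threshold acceptability rule (defaults 95 and 1e-5).
#' @param integer_n_pr draw N_PR as integer counts (default TRUE) or leave the
#'   truncated-Gaussian draws continuous.
#' @return a `risk_distribution` with `metric = "IR"`, or an object of class
#'   `risk_not_computable` when the category holds no carcinogen.
#' @export
simulate_ir <- function(inputs, exposure, iterations = 1000, seed,
                        percentile_used = 95, threshold = 1e-5,
                        integer_n_pr = TRUE) {
  stopifnot(inherits(inputs, "category_risk_inputs"),
            inherits(exposure, "exposure_model"), iterations >= 1)
  carcinogens <- names(inputs$tox)[vapply(inputs$tox, function(p) !is.na(p$iur),
                                          logical(1))]
  if (length(carcinogens) == 0) {
    return(structure(
      list(metric = "IR", category = inputs$category,
           reason = "not computable: no carcinogenic compound (no IUR) in this category"),
      class = "risk_not_computable"
    ))
  }
  cst <- exposure$constants
  npr_seed <- child_seed(seed, paste0("ir:n_pr:", inputs$category))
  n_pr <- if (integer_n_pr) {
    tg_sample_integer(exposure$spec_n_pr, iterations, npr_seed)
  } else {
    tg_sample(exposure$spec_n_pr, iterations, npr_seed)
  }
  f_s <- tg_sample(exposure$spec_f_s, iterations,
                   child_seed(seed, paste0("ir:f_s:", inputs$category)))
  n_y <- tg_sample(exposure$spec_n_y, iterations,
                   child_seed(seed, paste0("ir:n_y:", inputs$category)))
  fraction <- lifetime_exposure_fraction(n_y, f_s, n_pr, cst$n_r, cst$it_s,
                                         cst$at_days_per_year, cst$lt_years)
  risk_conc <- numeric(iterations) # sum of Cin_i * IUR_i per iteration
  for (id in sort(carcinogens)) {
    cs <- child_seed(seed, paste0("ir:cin:", inputs$category, ":", id))
    cin <- tg_sample(inputs$cin_specs[[id]], iterations, cs)
    risk_conc <- risk_conc + cin * inputs$tox[[id]]$iur
  }
  draws <- risk_conc * fraction
  summarize_draws(draws, percentile_used, threshold, "IR", inputs$category, seed)
}

#' @export
print.risk_not_computable <- function(x, ...) {
  cat(sprintf("%s for category %s: %s\n", x$metric, sQuote(x$category), x$reason))
  invisible(x)
}

#' Is a risk result a computed distribution?
#'
#' @param x result of [simulate_hi()] or [simulate_ir()].
#' @return `FALSE` for the explicit not-computable marker, `TRUE` for a
#'   `risk_distribution`.
#' @export
is_computable <- function(x) {
  inherits(x, "risk_distribution")
}

#' Empirical cumulative distribution function as a point series
#'
#' @param draws numeric vector (>= 1 value).
#' @return data frame `value`, `cum_prob`; `cum_prob` is non-decreasing and
#'   reaches exactly 1 at the maximum draw.
#' @export
empirical_cdf <- function(draws) {
  if (length(draws) < 1) stop("at least one draw is required")
  vals <- sort(unique(draws))
  data.frame(value = vals, cum_prob = stats::ecdf(draws)(vals))
}

#' Probability density histogram as a point series
#'
#' @param draws numeric vector (>= 1 value).
#' @param bins number of equal-width bins (default 30). A degenerate range
#'   (all draws equal) is widened to unit width around the common value.
#' @return data frame `bin_center`, `density`; densities integrate to 1.
#' @export
pdf_histogram <- function(draws, bins = 30) {
  if (length(draws) < 1) stop("at least one draw is required")
  stopifnot(bins >= 1)
  lo <- min(draws)
  hi <- max(draws)
  if (lo == hi) {
    lo <- lo - 0.5
    hi <- hi + 0.5
  }
  breaks <- seq(lo, hi, length.out = bins + 1)
  h <- graphics::hist(draws, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  data.frame(bin_center = h$mids, density = h$density)
}
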