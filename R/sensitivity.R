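#' Sup-norm distance between two empirical CDFs
#'
#' The two-sample Kolmogorov-Smirnov statistic: the empirical CDFs of the two
#' draw vectors are evaluated at every breakpoint of either sample and the
#' largest absolute difference is returned. Used to quantify the "overlap"
#' between replicate Monte Carlo runs.
#'
#' @param draws_a,draws_b non-empty numeric vectors.
#' @return scalar in [0, 1].
#' @export
cdf_sup_distance <- function(draws_a, draws_b) {
  if (length(draws_a) < 1 || length(draws_b) < 1) {
    stop("both draw vectors must be non-empty")
  }
  grid <- sort(unique(c(draws_a, draws_b)))
  fa <- stats::ecdf(draws_a)(grid)
  fb <- stats::ecdf(draws_b)(grid)
  max(abs(fa - fb))
}

#' Replicate a Monte Carlo risk simulation under independent seeds
#'
#' Reruns [simulate_hi()] (or [simulate_ir()]) `replicate_count` times with
#' sequential child seeds derived from `master_seed`; everything else is held
#' fixed, so the replicates differ only through the random streams. The whole
#' report is reproducible from `master_seed`.
#'
#' @param inputs a [category_risk_inputs()] object.
#' @param exposure an [exposure_model()]; required for `metric = "IR"`.
#' @param metric `"HI"` or `"IR"`.
#' @param iterations Monte Carlo iterations per replicate (default 1000).
#' @param replicate_count number of replicates (default 5, >= 2).
#' @param master_seed integer master seed.
#' @param ... passed to the simulation (thresholds, percentile).
#' @return list of `risk_distribution` objects (or `risk_not_computable`
#'   markers for an IR run on a carcinogen-free category).
#' @export
run_replicates <- function(inputs, exposure = NULL, metric = c("HI", "IR"),
                           iterations = 1000, replicate_count = 5,
                           master_seed, ...) {
  metric <- match.arg(metric)
  if (replicate_count < 2) stop("replicate_count must be >= 2")
  lapply(seq_len(replicate_count), function(i) {
    seed_i <- child_seed(master_seed, sprintf("replicate:%d", i))
    if (metric == "HI") {
      simulate_hi(inputs, iterations, seed_i, ...)
    } else {
      if (is.null(exposure)) stop("an exposure_model is required for IR replicates")
      simulate_ir(inputs, exposure, iterations, seed_i, ...)
    }
  })
}

#' Replicate sensitivity report
#'
#' Pairwise CDF sup distances between replicate runs; the run is declared
#' stable when the largest pairwise distance does not exceed `tolerance`.
#' The tolerance (default 0.05 at 1000 iterations) operationalizes "the
#' replicate CDFs overlap": it is a declared convention, configurable, not an
#' estimated quantity.
#'
#' @param replicates list of `risk_distribution` objects from
#'   [run_replicates()].
#' @param tolerance maximum acceptable pairwise distance (default 0.05).
#' @return an object of class `sensitivity_report`: metric, category,
#'   `replicate_count`, `pairwise_sup_distances` (symmetric matrix),
#'   `max_distance`, `stable`, `tolerance`.
#' @export
sensitivity_report <- function(replicates, tolerance = 0.05) {
  stopifnot(is.list(replicates), length(replicates) >= 2)
  if (!all(vapply(replicates, is_computable, logical(1)))) {
    stop("sensitivity report needs computed distributions ",
         "(the metric is not computable for this category)")
  }
  k <- length(replicates)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      d[i, j] <- d[j, i] <- cdf_sup_distance(replicates[[i]]$draws,
                                             replicates[[j]]$draws)
    }
  }
  structure(
    list(metric = replicates[[1]]$metric, category = replicates[[1]]$category,
         replicate_count = k, pairwise_sup_distances = d,
         max_distance = max(d), stable = max(d) <= tolerance,
         tolerance = tolerance),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf(
    "Sensitivity of %s for category %s: %d replicates, max KS distance %.4f (tolerance %.3f) -> %s\n",
    x$metric, sQuote(x$category), x$replicate_count, x$max_distance,
    x$tolerance, if (x$stable) "stable" else "UNSTABLE"))
  invisible(x)
}
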