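#' Truncated Gaussian specification
#'
#' Every randomized input of the Monte Carlo risk model (per-compound
#' inhalation concentration Cin_i, presentations per sample N_PR, samples per
#' year F_S, working years N_Y) is described by four descriptive statistics of
#' the observed data: mean `mu`, sample standard deviation `sigma`, and the
#' observed extremes `lower`/`upper`. Draws come from the normal law with
#' parameters (mu, sigma) restricted to [lower, upper]. Note the convention:
#' (mu, sigma) parameterize the *parent* normal, so the realized mean of the
#' truncated law generally differs from `mu` unless the truncation is wide or
#' symmetric.
#'
#' @param mu parent-normal location (the sample mean of the observations).
#' @param sigma parent-normal scale (sample SD, n-1 denominator; >= 0).
#' @param lower,upper truncation bounds (observed MIN and MAX).
#' @param n_obs number of observations behind the fit (optional).
#' @return an object of class `tg_spec`.
#' @export
tg_spec <- function(mu, sigma, lower, upper, n_obs = NA_integer_) {
  stopifnot(is.finite(mu), is.finite(sigma), is.finite(lower), is.finite(upper))
  if (sigma < 0) stop("sigma must be >= 0")
  if (lower > upper) stop("lower must be <= upper")
  out <- structure(
    list(mu = mu, sigma = sigma, lower = lower, upper = upper,
         n_obs = as.integer(n_obs)),
    class = "tg_spec"
  )
  if (mu < lower || mu > upper) {
    # legal but suspicious: the parent mean sits outside the truncation window
    attr(out, "mu_outside_bounds") <- TRUE
    warning("tg_spec: mu lies outside [lower, upper]; draws will pile up at a bound")
  }
  out
}

#' @export
print.tg_spec <- function(x, ...) {
  cat(sprintf("Truncated Gaussian: mu = %.6g, sigma = %.6g on [%.6g, %.6g]",
              x$mu, x$sigma, x$lower, x$upper))
  if (!is.na(x$n_obs)) cat(sprintf(" (fitted on n = %d)", x$n_obs))
  cat("\n")
  invisible(x)
}

#' Fit a truncated Gaussian specification to observations
#'
#' Descriptive-statistics fit: `mu` is the arithmetic mean, `sigma` the sample
#' standard deviation (n-1 denominator; 0 for a single observation), and the
#' truncation bounds are the observed extremes. A single observation therefore
#' yields a point mass.
#'
#' @param observations numeric vector, length >= 1.
#' @return a `tg_spec`.
#' @export
fit_tg_spec <- function(observations) {
  observations <- as.numeric(observations)
  if (length(observations) < 1) stop("at least one observation is required")
  if (any(!is.finite(observations))) stop("observations must be finite")
  s <- if (length(observations) > 1) stats::sd(observations) else 0
  tg_spec(mu = mean(observations), sigma = s,
          lower = min(observations), upper = max(observations),
          n_obs = length(observations))
}

#' Deterministic child seed from a master seed and a stream name
#'
#' Each randomized parameter and each compound consumes its own random stream,
#' keyed by a stable string, so that adding a compound (or running the IR
#' simulation after the HI one) never perturbs the other streams. The child
#' seed is a polynomial rolling hash of `"<master>:<name>"` reduced modulo
#' 2^31 - 1; it is exact in double arithmetic and stable across platforms.
#'
#' @param master_seed integer master seed.
#' @param name stream name (character scalar).
#' @return integer in [1, 2^31 - 1].
#' @export
child_seed <- function(master_seed, name) {
  stopifnot(length(name) == 1, is.character(name))
  key <- paste0(format(master_seed, scientific = FALSE), ":", name)
  bytes <- utf8ToInt(key)
  h <- 17
  m <- 2147483647 # 2^31 - 1 (prime)
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h + 1)
}

#' Draw from a truncated Gaussian specification
#'
#' Inverse-CDF sampling: u ~ Uniform(Phi(a), Phi(b)) with a, b the
#' standardized bounds, x = mu + sigma * Phi^-1(u). This avoids rejection
#' loops for narrow truncation windows and makes the draw an affine-equivariant
#' function of (mu, sigma) at a fixed seed. Every draw is clamped into
#' [lower, upper] to guard against floating-point spill in extreme tails.
#' `sigma = 0` yields `n` copies of `mu` clamped into the bounds.
#'
#' @param spec a `tg_spec`.
#' @param n number of draws (>= 0).
#' @param seed integer seed; identical (spec, n, seed) give identical draws.
#'   The caller's RNG state is left untouched.
#' @return numeric vector of length `n`, all values in [lower, upper].
#' @export
tg_sample <- function(spec, n, seed) {
  stopifnot(inherits(spec, "tg_spec"), n >= 0)
  n <- as.integer(n)
  if (n == 0) return(numeric(0))
  clamp <- function(x) pmin(pmax(x, spec$lower), spec$upper)
  if (spec$sigma == 0) return(rep(clamp(spec$mu), n))
  u <- with_seed(seed, stats::runif(n))
  a <- (spec$lower - spec$mu) / spec$sigma
  b <- (spec$upper - spec$mu) / spec$sigma
  pa <- stats::pnorm(a)
  pb <- stats::pnorm(b)
  x <- spec$mu + spec$sigma * stats::qnorm(pa + u * (pb - pa))
  clamp(x)
}

#' Draw integer counts from a truncated Gaussian specification
#'
#' For count-valued inputs (presentations per sample, N_PR): continuous draws
#' are rounded to the nearest integer, then clamped into
#' [max(ceiling(lower), 1), floor(upper)]. Rounding uses R's `round()`
#' (half-to-even).
#'
#' @inheritParams tg_sample
#' @return integer vector of length `n`, all values >= 1.
#' @export
tg_sample_integer <- function(spec, n, seed) {
  stopifnot(inherits(spec, "tg_spec"))
  hi <- floor(spec$upper)
  if (hi < 1) {
    stop("no valid presentation count: floor(upper) = ", hi, " is below 1")
  }
  lo <- max(ceiling(spec$lower), 1)
  x <- round(tg_sample(spec, n, seed))
  as.integer(pmin(pmax(x, lo), hi))
}

#' Closed-form quantile of a truncated Gaussian
#'
#' Phi^-1 applied on the renormalized interval [Phi(a), Phi(b)]. Used by the
#' analytic single-compound risk references against which the Monte Carlo
#' pipeline is validated.
#'
#' @param spec a `tg_spec`.
#' @param p probability (vectorized).
#' @return quantile(s) of the truncated law, clamped into [lower, upper].
#' @export
tg_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "tg_spec"), all(p >= 0 & p <= 1))
  if (spec$sigma == 0) {
    return(rep(pmin(pmax(spec$mu, spec$lower), spec$upper), length(p)))
  }
  a <- (spec$lower - spec$mu) / spec$sigma
  b <- (spec$upper - spec$mu) / spec$sigma
  pa <- stats::pnorm(a)
  pb <- stats::pnorm(b)
  x <- spec$mu + spec$sigma * stats::qnorm(pa + p * (pb - pa))
  pmin(pmax(x, spec$lower), spec$upper)
}

#' Flatten a list of specs to a data frame
#'
#' @param specs named list of `tg_spec` objects; names become the `scope`
#'   column (e.g. `"refinery/toluene"` or `"n_pr"`).
#' @return data frame: scope, mu, sigma, lower, upper, n_obs.
#' @export
tg_spec_table <- function(specs) {
  stopifnot(is.list(specs))
  do.call(rbind, lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    data.frame(scope = nm, mu = s$mu, sigma = s$sigma, lower = s$lower,
               upper = s$upper, n_obs = s$n_obs, stringsAsFactors = FALSE)
  }))
}

# Run `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
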