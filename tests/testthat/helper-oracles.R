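# Independent oracles, deliberately coded along different routes than the
# package internals they check.

# geometric mean via log-mean
geomean_oracle <- function(z) exp(mean(log(z)))

# two-pass sample variance, n-1 denominator
variance_oracle <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# mean and variance of a normal(mu, sigma) truncated to [lower, upper],
# by quadrature of x*phi(x)/Z and x^2*phi(x)/Z
tn_moments_quad <- function(mu, sigma, lower, upper) {
  z <- stats::integrate(function(x) stats::dnorm(x, mu, sigma),
                        lower, upper)$value
  m1 <- stats::integrate(function(x) x * stats::dnorm(x, mu, sigma),
                         lower, upper)$value / z
  m2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, mu, sigma),
                         lower, upper)$value / z
  list(mean = m1, var = m2 - m1^2)
}

# quantile of the truncated normal by numerical inversion (uniroot on the
# renormalized CDF), not by the qnorm shortcut the package uses
tn_quantile_oracle <- function(mu, sigma, lower, upper, p) {
  za <- stats::pnorm(lower, mu, sigma)
  zb <- stats::pnorm(upper, mu, sigma)
  cdf <- function(x) (stats::pnorm(x, mu, sigma) - za) / (zb - za)
  stats::uniroot(function(x) cdf(x) - p, c(lower, upper),
                 tol = 1e-12)$root
}

# two-sample CDF sup distance by brute-force evaluation of both step
# functions at every breakpoint
ks_brute_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# bootstrap standard error of an empirical quantile
quantile_boot_se <- function(draws, p, reps = 200, seed = 1) {
  set.seed(seed)
  qs <- replicate(reps, stats::quantile(sample(draws, replace = TRUE), p,
                                        names = FALSE, type = 7))
  stats::sd(qs)
}
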