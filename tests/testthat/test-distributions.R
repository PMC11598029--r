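test_that("fitting reduces observations to mean, sd and observed extremes", {
  s <- fit_tg_spec(c(5, 5, 5))
  expect_equal(c(s$mu, s$sigma, s$lower, s$upper), c(5, 0, 5, 5))

  x <- c(2, 4, 6, 8)
  s2 <- fit_tg_spec(x)
  expect_equal(s2$mu, 5)
  expect_equal(s2$sigma, sqrt(variance_oracle(x)))
  expect_equal(c(s2$lower, s2$upper), c(2, 8))

  s3 <- fit_tg_spec(7)
  expect_equal(c(s3$mu, s3$sigma), c(7, 0))
  expect_equal(s3$n_obs, 1L)

  expect_error(fit_tg_spec(numeric(0)), "at least one")
})

test_that("draws always respect the truncation bounds", {
  set.seed(31)
  for (i in 1:8) {
    mu <- stats::rnorm(1, 0, 10)
    sigma <- stats::rexp(1, 0.2)
    lo <- mu + stats::rnorm(1, -1, 2) * sigma
    hi <- lo + stats::rexp(1, 0.1) * sigma
    spec <- suppressWarnings(tg_spec(mu, sigma, lo, hi))
    x <- tg_sample(spec, 2000, seed = 100 + i)
    expect_gte(min(x), lo)
    expect_lte(max(x), hi)
  }
})

test_that("degenerate and empty draws behave as point mass and empty vector", {
  spec <- tg_spec(5, 0, 5, 5)
  expect_equal(tg_sample(spec, 4, seed = 1), rep(5, 4))
  expect_identical(tg_sample(spec, 0, seed = 1), numeric(0))
  # sigma 0 with mu outside the bounds clamps to the nearer bound
  spec2 <- suppressWarnings(tg_spec(9, 0, 1, 3))
  expect_equal(tg_sample(spec2, 2, seed = 1), c(3, 3))
})

test_that("sampling is seed-deterministic and leaves the caller RNG alone", {
  spec <- tg_spec(10, 3, 2, 20)
  a <- tg_sample(spec, 500, seed = 42)
  b <- tg_sample(spec, 500, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, tg_sample(spec, 500, seed = 43)))

  set.seed(77)
  before <- stats::runif(5)
  set.seed(77)
  invisible(tg_sample(spec, 100, seed = 42))
  after <- stats::runif(5)
  expect_identical(before, after)
})

test_that("sample moments match quadrature of the truncated density", {
  spec <- tg_spec(0, 1, -1, 1)
  n <- 1e5
  x <- tg_sample(spec, n, seed = 7)
  mom <- tn_moments_quad(0, 1, -1, 1)
  se_mean <- sqrt(mom$var / n)
  expect_lt(abs(mean(x) - mom$mean), 3 * se_mean)
  # variance of the sample variance ~ 2*var^2/(n-1) for near-normal data;
  # the truncated law is platykurtic so this bound is conservative enough
  expect_lt(abs(stats::var(x) - mom$var), 3 * sqrt(2) * mom$var / sqrt(n - 1))
})

test_that("wide truncation recovers the parent normal moments", {
  spec <- tg_spec(50, 4, 50 - 40, 50 + 40)
  n <- 1e5
  x <- tg_sample(spec, n, seed = 13)
  expect_lt(abs(mean(x) - 50), 3 * 4 / sqrt(n))
  expect_lt(abs(stats::sd(x) - 4), 0.05)
})

test_that("fitting draws from a known spec recovers its parameters", {
  spec <- tg_spec(20, 5, 10, 35)
  x <- tg_sample(spec, 1e4, seed = 3)
  fit <- fit_tg_spec(x)
  expect_gte(fit$lower, spec$lower)
  expect_lte(fit$upper, spec$upper)
  mom <- tn_moments_quad(20, 5, 10, 35)
  expect_lt(abs(fit$mu - mom$mean), 3 * sqrt(mom$var / 1e4))
})

test_that("integer draws round, clamp to >= 1 and fail without valid counts", {
  spec <- tg_spec(9.6, 0.3, 8.8, 10.4)
  x <- tg_sample_integer(spec, 5000, seed = 5)
  expect_true(all(x %in% c(9L, 10L)))
  # rounding of the continuous draws dominates: both values must occur
  expect_true(all(c(9L, 10L) %in% x))

  spec0 <- tg_spec(7.4, 0, 7.4, 7.4)
  expect_equal(tg_sample_integer(spec0, 3, seed = 1), rep(7L, 3))

  expect_error(tg_sample_integer(tg_spec(0.2, 0.1, 0, 0.4), 10, seed = 1),
               "presentation count")
})

test_that("closed-form truncated quantiles agree with numerical CDF inversion", {
  cases <- list(c(0, 1, -1, 1), c(10, 3, 5, 30), c(-2, 0.5, -2.4, -1))
  for (cs in cases) {
    spec <- tg_spec(cs[1], cs[2], cs[3], cs[4])
    for (p in c(0.05, 0.5, 0.95)) {
      expect_equal(tg_quantile(spec, p),
                   tn_quantile_oracle(cs[1], cs[2], cs[3], cs[4], p),
                   tolerance = 1e-8)
    }
  }
})

test_that("child seeds are stable, name-sensitive and in integer range", {
  expect_identical(child_seed(42, "hi:cin:refinery:toluene"),
                   child_seed(42, "hi:cin:refinery:toluene"))
  expect_false(child_seed(42, "a") == child_seed(42, "b"))
  expect_false(child_seed(42, "a") == child_seed(43, "a"))
  seeds <- vapply(letters, function(l) child_seed(1, l), integer(1))
  expect_true(all(seeds >= 1 & seeds <= 2147483647))
})
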