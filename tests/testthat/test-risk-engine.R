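test_that("hazard quotient and hazard index follow their definitions", {
  expect_equal(hazard_quotient(500, 500), 1)
  expect_equal(hazard_quotient(0, 500), 0)
  # 8-h OEL of 75 mg/m3, inhaled 20 ug/m3
  expect_equal(hazard_quotient(20, canonicalize_concentration(75, "mg/m3")),
               20 / 75000)
  expect_error(hazard_quotient(1, 0), "OEL")

  expect_equal(hazard_index(c(0.1, 0.2, 0.3)), 0.6)
  expect_equal(hazard_index(numeric(0)), 0)
  expect_equal(hazard_index(rep(0.01, 100)), 1.0, tolerance = 1e-12)
  expect_error(hazard_index(c(0.1, -0.2)))
})

test_that("lifetime exposure fraction is dimensionless and linear", {
  f <- lifetime_exposure_fraction(5, 100, 10, 3, 3)
  expect_equal(f, (5 * 100 * 10 * 3 * (3 / 86400)) / (365 * 70))
  expect_equal(lifetime_exposure_fraction(5, 100, 20, 3, 3), 2 * f)
  # cancellation: a full day of inhalation per unit over the whole window
  expect_equal(lifetime_exposure_fraction(25550, 1, 1, 1, 86400), 1)
  expect_error(lifetime_exposure_fraction(0, 1, 1, 1, 1), "> 0")
})

test_that("inhalation risk multiplies concentration, fraction and IUR", {
  expect_equal(inhalation_risk(10, 0, 0.5), 0)
  expect_equal(inhalation_risk(10, 5e-6, 2e-5), 1e-9)
  expect_equal(inhalation_risk(1, 3e-6, 1), 3e-6)
  expect_error(inhalation_risk(-1, 1e-6, 1))
})

test_that("degenerate specs collapse the HI simulation to its point value", {
  inputs <- make_inputs(list(cmpd = tg_spec(500, 0, 500, 500)), oel_ug = 1000)
  r <- simulate_hi(inputs, iterations = 200, seed = 1)
  expect_true(all(r$draws == 0.5))
  expect_equal(r$summary[["p95"]], 0.5)
  expect_true(r$verdict)

  two <- category_risk_inputs(
    "two",
    list(a = tg_spec(100, 0, 100, 100), b = tg_spec(300, 0, 300, 300)),
    make_tox(c("a", "b"), oel_ug = c(1000, 1000))
  )
  r2 <- simulate_hi(two, iterations = 50, seed = 1)
  expect_true(all(r2$draws == 0.1 + 0.3))
})

test_that("simulated HI p95 matches the closed-form truncated quantile", {
  spec <- tg_spec(40, 15, 5, 90)
  oel <- 1000
  inputs <- make_inputs(list(cmpd = spec), oel_ug = oel)
  r <- simulate_hi(inputs, iterations = 1e4, seed = 9)
  q_ref <- tn_quantile_oracle(40, 15, 5, 90, 0.95) / oel
  se <- quantile_boot_se(r$draws, 0.95)
  expect_lt(abs(r$summary[["p95"]] - q_ref), 3 * se)
})

test_that("HI simulation requires at least one compound with an OEL", {
  # a carcinogen with an IUR but no OEL is usable for IR yet not for HI
  tox <- make_tox("noOel", oel_ug = NA_real_, iur = 1e-6)
  inputs <- category_risk_inputs("c", list(noOel = tg_spec(1, 0, 1, 1)), tox)
  expect_error(simulate_hi(inputs, 10, seed = 1), "noOel")
})

test_that("HI draw means converge to the quadrature expectation", {
  specs <- list(a = tg_spec(40, 15, 5, 90), b = tg_spec(10, 4, 1, 25))
  inputs <- category_risk_inputs("c", specs,
                                 make_tox(c("a", "b"), oel_ug = c(500, 200)))
  r <- simulate_hi(inputs, iterations = 1e4, seed = 2)
  ma <- tn_moments_quad(40, 15, 5, 90)
  mb <- tn_moments_quad(10, 4, 1, 25)
  expected <- ma$mean / 500 + mb$mean / 200
  se <- sqrt((ma$var / 500^2 + mb$var / 200^2) / 1e4)
  expect_lt(abs(mean(r$draws) - expected), 3 * se)
})

test_that("a category without carcinogens yields the explicit IR marker", {
  inputs <- make_inputs(list(cmpd = tg_spec(10, 2, 5, 15)), oel_ug = 1000)
  r <- simulate_ir(inputs, degenerate_exposure(), iterations = 100, seed = 1)
  expect_s3_class(r, "risk_not_computable")
  expect_false(is_computable(r))
  expect_match(r$reason, "no carcinogenic compound")
})

test_that("fully degenerate IR inputs reproduce the deterministic risk exactly", {
  iur <- 7.8e-6
  inputs <- make_inputs(list(cmpd = tg_spec(12, 0, 12, 12)), oel_ug = 1000,
                        iur = iur)
  exp_model <- degenerate_exposure(n_pr = 10, f_s = 100, n_y = 5)
  r <- simulate_ir(inputs, exp_model, iterations = 100, seed = 1)
  f <- lifetime_exposure_fraction(5, 100, 10, 3, 3)
  expect_true(all(r$draws == 12 * iur * f))
})

test_that("IR median matches the scaled closed-form median under degenerate exposure", {
  iur <- 5e-6
  spec <- tg_spec(30, 10, 8, 60)
  inputs <- make_inputs(list(cmpd = spec), oel_ug = 1e6, iur = iur)
  exp_model <- degenerate_exposure(n_pr = 10, f_s = 100, n_y = 5)
  r <- simulate_ir(inputs, exp_model, iterations = 1e4, seed = 4)
  f <- lifetime_exposure_fraction(5, 100, 10, 3, 3)
  ref <- tn_quantile_oracle(30, 10, 8, 60, 0.5) * iur * f
  se <- quantile_boot_se(r$draws, 0.5)
  expect_lt(abs(r$summary[["p50"]] - ref), 3 * se)
})

test_that("scaling the safety factor scales every HI and IR draw linearly", {
  # doubling k doubles every fitted Cin spec parameter, hence every draw
  scale_spec <- function(s, c) tg_spec(s$mu * c, s$sigma * c,
                                       s$lower * c, s$upper * c, s$n_obs)
  spec <- tg_spec(40, 15, 5, 90)
  i1 <- make_inputs(list(cmpd = spec), oel_ug = 1000, iur = 1e-6)
  i2 <- make_inputs(list(cmpd = scale_spec(spec, 2)), oel_ug = 1000, iur = 1e-6)
  h1 <- simulate_hi(i1, 500, seed = 6)
  h2 <- simulate_hi(i2, 500, seed = 6)
  expect_equal(h2$draws, 2 * h1$draws, tolerance = 1e-12)
  ex <- degenerate_exposure()
  r1 <- simulate_ir(i1, ex, 500, seed = 6)
  r2 <- simulate_ir(i2, ex, 500, seed = 6)
  expect_equal(r2$draws, 2 * r1$draws, tolerance = 1e-12)
})

test_that("raising an OEL lowers HI draws; raising an IUR raises IR draws", {
  spec <- list(cmpd = tg_spec(40, 15, 5, 90))
  h_lo <- simulate_hi(make_inputs(spec, oel_ug = 500), 300, seed = 8)
  h_hi <- simulate_hi(make_inputs(spec, oel_ug = 800), 300, seed = 8)
  expect_true(all(h_hi$draws <= h_lo$draws))
  ex <- degenerate_exposure()
  r_lo <- simulate_ir(make_inputs(spec, iur = 1e-6), ex, 300, seed = 8)
  r_hi <- simulate_ir(make_inputs(spec, iur = 2e-6), ex, 300, seed = 8)
  expect_true(all(r_hi$draws >= r_lo$draws))
})

test_that("assuming full concentration at every presentation is conservative", {
  # reference model: the j-th of N_PR presentations occurs one dilution step
  # below the next, so exposure sums to Cin * (2 - 2^(1 - N_PR)) < Cin * N_PR
  iur <- 1e-6
  n_pr <- 10
  inputs <- make_inputs(list(cmpd = tg_spec(30, 10, 8, 60)), iur = iur)
  ex <- degenerate_exposure(n_pr = n_pr, f_s = 100, n_y = 5)
  r <- simulate_ir(inputs, ex, 1000, seed = 10)
  cs <- child_seed(10, "ir:cin:testcat:cmpd")
  cin <- tg_sample(inputs$cin_specs$cmpd, 1000, cs)
  ladder_factor <- 2 - 2^(1 - n_pr)
  f_per_presentation <- lifetime_exposure_fraction(5, 100, 1, 3, 3)
  ladder_ir <- cin * iur * f_per_presentation * ladder_factor
  expect_true(all(ladder_ir < r$draws))
})

test_that("summaries interpolate order statistics and verdicts are strict", {
  s <- summarize_draws(1:100, 95, threshold = 100, metric = "HI")
  expect_equal(s$summary[["p95"]], 95.05) # 95th + 0.05 * gap, hand-computed
  expect_equal(s$summary[["p50"]], 50.5)

  const <- summarize_draws(rep(2, 10), 95, threshold = 2, metric = "HI")
  expect_true(all(const$summary[c("p25", "p50", "p75", "p95")] == 2))
  expect_false(const$verdict) # quantile == threshold is unacceptable
  below <- summarize_draws(rep(2, 10), 95, threshold = 2.0001, metric = "HI")
  expect_true(below$verdict)

  expect_error(summarize_draws(numeric(0), 95, 1, "HI"), "at least one")
})

test_that("HI and IR consume independent random streams", {
  inputs <- make_inputs(list(cmpd = tg_spec(40, 15, 5, 90)), iur = 1e-6)
  hi_alone <- simulate_hi(inputs, 200, seed = 12)
  invisible(simulate_ir(inputs, degenerate_exposure(), 200, seed = 12))
  hi_after <- simulate_hi(inputs, 200, seed = 12)
  expect_identical(hi_alone$draws, hi_after$draws)
})

test_that("empirical CDF and density histogram are normalized", {
  cdf <- empirical_cdf(c(1, 2, 3, 4))
  expect_equal(cdf$cum_prob, c(0.25, 0.5, 0.75, 1.0))
  expect_true(all(diff(cdf$cum_prob) >= 0))

  draws <- tg_sample(tg_spec(10, 3, 2, 20), 500, seed = 14)
  cdf2 <- empirical_cdf(draws)
  expect_equal(cdf2$cum_prob[nrow(cdf2)], 1.0)

  h1 <- pdf_histogram(draws, bins = 1)
  width <- max(draws) - min(draws)
  expect_equal(h1$density, 1 / width)
  h <- pdf_histogram(draws, bins = 17)
  expect_equal(sum(h$density) * (width / 17), 1, tolerance = 1e-12)

  expect_error(empirical_cdf(numeric(0)))
  expect_error(pdf_histogram(numeric(0)))
})
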