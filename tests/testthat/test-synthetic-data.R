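test_that("characterized sample counts are exact and the dataset is deterministic", {
  sc <- single_compound_scenario(n_samples = 401, chem_fraction = 0.25)
  ds <- generate_dataset(sc)
  expect_equal(nrow(ds$characterized), round(0.25 * 401))
  expect_equal(nrow(ds$odor), 401)
  # chemistry rows only for characterized samples
  expect_true(all(ds$samples$sample_id %in% ds$characterized$sample_id))

  ds2 <- generate_dataset(sc)
  expect_identical(ds, ds2)
  sc3 <- single_compound_scenario(n_samples = 401, chem_fraction = 0.25,
                                  master_seed = 8)
  expect_false(identical(generate_dataset(sc3)$odor, ds$odor))
})

test_that("a degenerate generator produces identical concentrations", {
  sc <- syn_scenario(
    list(syn_category("flat", 40, 1,
                      list(syn_compound("c1", log(100), 0, detect_prob = 1,
                                        oel_value_mg = 10)),
                      odor_meanlog = log(300), odor_sdlog = 0)),
    syn_panel(3, tg_spec(5, 0, 5, 5), tg_spec(50, 0, 50, 50),
              tg_spec(8, 0, 8, 8), analyses_per_panelist = 4),
    master_seed = 3
  )
  ds <- generate_dataset(sc)
  expect_equal(nrow(ds$samples), 40) # every sample characterized and detected
  expect_equal(ds$samples$concentration, rep(100, 40))
  expect_equal(ds$odor$odor_concentration, rep(300, 40))
  expect_true(all(ds$presentations$n_presentations == 8))
})

test_that("concentration caps act as truncation guards", {
  sc <- syn_scenario(
    list(syn_category("capped", 200, 1,
                      list(syn_compound("c1", log(100), 2, detect_prob = 1,
                                        oel_value_mg = 10, conc_cap = 500)),
                      odor_meanlog = log(300), odor_sdlog = 0.5)),
    syn_panel(3, tg_spec(5, 0, 5, 5), tg_spec(50, 0, 50, 50),
              tg_spec(8, 0, 8, 8)),
    master_seed = 4
  )
  ds <- generate_dataset(sc)
  expect_lte(max(ds$samples$concentration), 500)
})

test_that("the closed-form reference handles symmetry, quantiles and no-IUR", {
  # symmetric truncation: the median is exactly mu
  spec <- tg_spec(50, 10, 30, 70)
  inputs <- make_inputs(list(cmpd = spec), oel_ug = 200)
  ref <- analytic_reference_risk(inputs, degenerate_exposure(),
                                 hi_percentile = 50)
  expect_equal(ref$hi, 50 / 200)
  expect_false(is_computable(ref$ir))

  # asymmetric case against the numerical inverse oracle
  spec2 <- tg_spec(40, 15, 5, 90)
  inputs2 <- make_inputs(list(cmpd = spec2), oel_ug = 1000, iur = 2e-6)
  ref2 <- analytic_reference_risk(inputs2, degenerate_exposure())
  expect_equal(ref2$hi, tn_quantile_oracle(40, 15, 5, 90, 0.95) / 1000,
               tolerance = 1e-8)
  f <- lifetime_exposure_fraction(5, 100, 10, 3, 3)
  expect_equal(ref2$ir, tn_quantile_oracle(40, 15, 5, 90, 0.5) * 2e-6 * f,
               tolerance = 1e-8)
})

test_that("the closed-form reference rejects unsupported configurations", {
  two <- category_risk_inputs(
    "two", list(a = tg_spec(1, 0, 1, 1), b = tg_spec(2, 0, 2, 2)),
    make_tox(c("a", "b"), oel_ug = c(10, 10)))
  expect_error(analytic_reference_risk(two, degenerate_exposure()),
               "exactly one compound")

  one <- make_inputs(list(cmpd = tg_spec(5, 1, 3, 8)), oel_ug = 10, iur = 1e-6)
  wobbly <- exposure_model(lab_constants(),
                           spec_n_pr = tg_spec(10, 1, 8, 12),
                           spec_f_s = tg_spec(100, 0, 100, 100),
                           spec_n_y = tg_spec(5, 0, 5, 5))
  expect_error(analytic_reference_risk(one, wobbly), "degenerate")
})

test_that("the default scenario mirrors the survey structure", {
  sc <- default_scenario(1)
  n_total <- sum(vapply(sc$categories, `[[`, integer(1), "n_samples"))
  expect_equal(n_total, 1035L)
  expect_length(sc$categories, 13)
  expect_true(all(vapply(sc$categories, `[[`, numeric(1), "chem_fraction") == 0.25))
  # exactly the two expected categories lack carcinogens
  has_iur <- vapply(sc$categories, function(cat) {
    any(!is.na(vapply(cat$compounds, `[[`, numeric(1), "iur")))
  }, logical(1))
  expect_setequal(names(which(!has_iur)), c("wwtp", "biofuel"))
})
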