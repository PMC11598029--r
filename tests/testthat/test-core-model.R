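test_that("concentration canonicalization scales mg/m3 and fixes ug/m3", {
  expect_equal(canonicalize_concentration(1.0, "mg/m3"), 1000)
  expect_equal(canonicalize_concentration(13.79, "ug/m3"), 13.79)
  expect_equal(canonicalize_concentration(0, "mg/m3"), 0)
  # unicode spellings map onto the same tokens
  expect_equal(canonicalize_concentration(2, "µg/m³"), 2)
  expect_equal(canonicalize_concentration(2, "mg/m³"), 2000)
  expect_error(canonicalize_concentration(1, "ppm"), "ppm")
  expect_error(canonicalize_concentration(-1, "ug/m3"), "non-negative")
})

test_that("mg/m3 -> ug/m3 -> mg/m3 round-trips to machine precision", {
  vals <- c(0, 1e-6, 0.37, 13.79, 75, 1e4)
  back <- canonicalize_concentration(vals, "mg/m3") / 1000
  expect_equal(back, vals, tolerance = 1e-15)
})

test_that("tox table keeps the short-term OEL active with the 8-h as fallback", {
  tox <- load_tox_table(data.frame(
    compound_id = c("toluene", "h2s", "h2s"),
    oel_value = c(75, 7, 14),
    oel_unit = "mg/m3",
    oel_kind = c("twa_8h", "twa_8h", "short_term_15min"),
    iur = NA_real_, iur_unit = "per_ug_m3", source_note = ""
  ))
  # 8-h value adopted when no short-term limit exists, converted to ug/m3
  expect_equal(tox[["toluene"]]$oel_value, 75000)
  expect_equal(tox[["toluene"]]$oel_kind, "twa_8h")
  # short-term retained as active, 8-h kept as fallback metadata
  expect_equal(tox[["h2s"]]$oel_value, 14000)
  expect_equal(tox[["h2s"]]$oel_kind, "short_term_15min")
  expect_equal(tox[["h2s"]]$oel_twa8h_fallback, 7000)
})

test_that("tox rows with invalid OELs are rejected with a diagnostic", {
  tox <- load_tox_table(data.frame(
    compound_id = c("bad0", "badunit", "ok"),
    oel_value = c(0, 10, 10),
    oel_unit = c("mg/m3", "ppb", "mg/m3"),
    oel_kind = "twa_8h",
    iur = NA_real_, iur_unit = "per_ug_m3", source_note = ""
  ))
  rej <- attr(tox, "rejected")
  expect_setequal(rej$compound_id, c("bad0", "badunit"))
  expect_true(any(grepl("non-positive", rej$reason)))
  expect_true(any(grepl("unit", rej$reason)))
  expect_named(tox, "ok")
})

test_that("compound resolution is total: every id is resolved or excluded", {
  tox <- load_tox_table(data.frame(
    compound_id = c("a", "b", "noinfo"),
    oel_value = c(10, NA, NA),
    oel_unit = "mg/m3", oel_kind = "twa_8h",
    iur = c(NA, 5e-6, NA), iur_unit = "per_ug_m3", source_note = ""
  ))
  # b has an IUR only: usable; noinfo has neither: flagged
  expect_setequal(attr(tox, "unusable"), "noinfo")
  res <- resolve_compounds(tox, c("a", "b", "noinfo", "unknown"))
  expect_setequal(names(res$resolved), c("a", "b"))
  expect_setequal(res$excluded$compound_id, c("noinfo", "unknown"))
  expect_equal(length(res$resolved) + nrow(res$excluded), 4)
})

test_that("IUR units are canonicalized to per (ug/m3)", {
  tox <- load_tox_table(data.frame(
    compound_id = c("x", "y"), oel_value = 10, oel_unit = "mg/m3",
    oel_kind = "twa_8h", iur = c(7.8e-6, 7.8e-3),
    iur_unit = c("per_ug_m3", "per_mg_m3"), source_note = ""
  ))
  expect_equal(tox[["x"]]$iur, tox[["y"]]$iur)
})

test_that("sample set readers validate identity and positivity constraints", {
  samples <- data.frame(sample_id = c("s1", "s1", "s2"),
                        category = "cat", compound_id = c("a", "b", "a"),
                        concentration = c(1, 2, 3), unit = "mg/m3")
  odor <- data.frame(sample_id = c("s1", "s2", "s3"),
                     odor_concentration = c(100, 200, 400))
  ss <- read_sample_set(samples, odor)
  expect_equal(ss$chemistry$concentration, c(1000, 2000, 3000))
  expect_equal(nrow(ss$odor), 3) # uncharacterized s3 retained

  expect_error(read_sample_set(samples, odor[1, , drop = FALSE]),
               "without an odor concentration")
  odor_dup <- rbind(odor, odor[1, ])
  expect_error(read_sample_set(samples, odor_dup), "duplicate")
  odor_bad <- transform(odor, odor_concentration = c(100, 0, 400))
  expect_error(read_sample_set(samples, odor_bad), "> 0")
})

test_that("panel survey reader enforces positive exposure observations", {
  survey <- data.frame(panelist_id = "p1", working_years = 5,
                       samples_per_year = 100)
  pres <- data.frame(panelist_id = "p1", sample_id = "s1", n_presentations = 8)
  expect_s3_class(read_panel_survey(survey, pres), "panel_survey")
  expect_error(read_panel_survey(transform(survey, working_years = 0), pres))
  expect_error(read_panel_survey(survey, transform(pres, n_presentations = 0.5)))
})
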