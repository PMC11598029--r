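# In-code fixtures shared across test files.

# minimal tox table: one compound, OEL given directly in ug/m3
make_tox <- function(compound_id = "cmpd", oel_ug = 1000, iur = NA_real_,
                     oel_kind = "short_term_15min") {
  load_tox_table(data.frame(
    compound_id = compound_id, oel_value = oel_ug, oel_unit = "ug/m3",
    oel_kind = oel_kind, iur = iur, iur_unit = "per_ug_m3",
    source_note = "test fixture", stringsAsFactors = FALSE
  ))
}

# category risk inputs around explicit tg specs
make_inputs <- function(specs, oel_ug = 1000, iur = NA_real_,
                        category = "testcat") {
  tox <- make_tox(names(specs), oel_ug, iur)
  category_risk_inputs(category, specs, tox)
}

# exposure model with point-mass (sigma 0) parameter specs
degenerate_exposure <- function(n_pr = 10, f_s = 100, n_y = 5,
                                constants = lab_constants()) {
  exposure_model(
    constants,
    spec_n_pr = tg_spec(n_pr, 0, n_pr, n_pr),
    spec_f_s = tg_spec(f_s, 0, f_s, f_s),
    spec_n_y = tg_spec(n_y, 0, n_y, n_y)
  )
}

# one-category, one-compound synthetic scenario
single_compound_scenario <- function(n_samples = 400, meanlog = log(500),
                                     sdlog = 0.8, oel_mg = 10,
                                     iur = NA_real_, master_seed = 7,
                                     chem_fraction = 0.5) {
  syn_scenario(
    categories = list(syn_category(
      "solo", n_samples, chem_fraction,
      list(syn_compound("cmpd", meanlog, sdlog, detect_prob = 1,
                        oel_value_mg = oel_mg, oel_kind = "short_term_15min",
                        iur = iur)),
      odor_meanlog = log(400), odor_sdlog = 0.7
    )),
    panel = syn_panel(
      n_panelists = 8,
      spec_n_y = tg_spec(5, 0, 5, 5),
      spec_f_s = tg_spec(100, 0, 100, 100),
      spec_n_pr = tg_spec(10, 0, 10, 10),
      analyses_per_panelist = 10
    ),
    master_seed = master_seed
  )
}
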