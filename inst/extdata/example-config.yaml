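# Example olfrisk run configuration.
# Exactly one input source: either `scenario: default` (built-in synthetic
# laboratory) or a `data:` block with five CSV paths (relative paths are
# resolved against this file's directory).
scenario: default
# data:
#   samples: samples.csv          # sample_id, category, compound_id, concentration, unit
#   odor: odor.csv                # sample_id, odor_concentration
#   tox: tox.csv                  # compound_id, oel_value, oel_unit, oel_kind, iur, iur_unit, source_note
#   survey: survey.csv            # panelist_id, working_years, samples_per_year
#   presentations: presentations.csv  # panelist_id, sample_id, n_presentations

iterations: 1000
master_seed: 42
percentile_used: 95
hi_threshold: 1
ir_threshold: 1.0e-5
replicate_count: 5
sensitivity_tolerance: 0.05

constants:
  n_r: 3                # rounds per sample
  it_s: 3               # inhalation (presentation) time, seconds
  safety_factor_k: 10   # deltaZ_max x confirmation factor
  at_days_per_year: 365
  lt_years: 70
  delta_z_max: 5
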