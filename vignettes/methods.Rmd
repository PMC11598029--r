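---
title: "Probabilistic risk assessment for olfactometry panels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic risk assessment for olfactometry panels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfrisk)
```

## The exposure scenario

Dynamic olfactometry presents an odorous air sample to a panel of human
assessors at stepwise decreasing dilutions (the concentration doubles
between consecutive presentations) until each assessor perceives it and
confirms the perception at the next, twice-as-concentrated presentation.
The odor concentration of the sample, `C_od` in ou~E~/m³, is the geometric
mean of the individual threshold estimates (Z~ITE~, dilution factors)
multiplied by the square root of the dilution step: the true threshold lies
between the last undetected and first detected presentation, half a step
apart on the log scale. A valid measurement needs at least 12 Z~ITE~; with
the minimum panel of 4 assessors that means at least 3 rounds
(`compute_odor_concentration()`, `required_threshold_count()`).

Panelists therefore inhale untreated sample at concentrations up to the
panel threshold level. Two protocol features make individual exposure worse
than the panel average: retrospective screening tolerates an individual
threshold up to `ΔZ_max = 5` times the panel geometric mean
(`screen_panel()`), and the confirmation presentation doubles the
concentration. Their product is the conservative safety factor
`k = 5 × 2 = 10` (`compute_safety_factor()`), and the assessed inhalation
concentration of compound *i* is `Cin_i = (C_i / C_od) · k`
(`compute_inhalation_concentration()`).

On the ΔZ screening rule: the bound is printed as `−5 ≤ ΔZ ≤ +5` with ΔZ
defined as a plain ratio of positive dilution factors, so the lower bound
can never bind. The underlying standard plausibly intends a log-scale
deviation, for which −5 would be meaningful, but we implement the rule as
stated (closed bounds, plain ratio) rather than guessing intent;
`screen_panel()` is the single seam where a log-scale variant could be
swapped in.

## Risk model

Non-carcinogenic risk is the hazard index `HI = Σ_i Cin_i / OEL_i`
(`simulate_hi()`). The occupational exposure limit hierarchy prefers a
short-term (15 min) value — the exposure lasts seconds — and falls back on
the 8-h time-weighted average when no short-term value exists; since 8-h
limits are lower, the fallback can only overstate risk
(`load_tox_table()`). HI deliberately ignores exposure duration and
frequency: it compares a concentration to a concentration limit.

Carcinogenic risk is the inhalation risk
`IR = Σ_i Cin_i · IUR_i · f`, where the lifetime exposure fraction
`f = (N_Y · F_S · N_PR · N_R · IT/86400) / (AT · LT)` converts per-analysis
inhalation seconds into a fraction of the 70-year regulatory averaging
window (`lifetime_exposure_fraction()`; AT = 365 days/year, LT = 70 years).
The seconds-to-days conversion (86 400 s/day) is the only dimensionally
consistent reading of this ratio and is fixed in code. Compounds without an
inhalation unit risk are non-carcinogens; a category with no carcinogen at
all yields an explicit "not computable" marker instead of a zero
(`simulate_ir()`), so the absence of information is never silently
converted into an absence of risk.

Three conservative assumptions are structural: every presentation is
assumed to occur at the full confirmation-level concentration, with no
discount for the ascending dilution ladder (a ladder-aware model would
multiply per-sample exposure by `2 − 2^(1−N_PR)` instead of `N_PR`, always
less for `N_PR > 1`; the test suite verifies the inequality); the global
panel survey is applied to every category as if all samples belonged to it;
and `k` treats the worst admissible assessor deviation as occurring at
every measurement.

## Randomization

Every variable input — `Cin_i` per (category, compound), `N_PR`, `F_S`,
`N_Y` — is described by four descriptive statistics of observed data: mean,
sample standard deviation (n−1 denominator; a single observation gives a
point mass), minimum and maximum (`fit_tg_spec()`). Draws come from the
normal law with those two moments truncated to the observed extremes. Note
the convention choice: (μ, σ) parameterize the *parent* normal, so the
realized mean of the truncated law differs from μ when the truncation is
asymmetric. The alternative — moment-matching the truncated law itself —
was rejected as a reinterpretation of the stated procedure; tests account
for the discrepancy by comparing against quadrature of the truncated
density, not against μ directly.

Sampling is by inverse CDF on the renormalized interval
(`u ~ U[Φ(a), Φ(b)]`, `x = μ + σΦ⁻¹(u)`), which has no rejection loop to
diverge on narrow windows, makes draws affine-equivariant in (μ, σ) at a
fixed seed (hence doubling `k` exactly doubles every HI and IR draw), and
clamps against floating-point spill at extreme tails. Fitted
concentration specs use *detected* values only: treating absence as zero
would drag every lower bound to 0 and distort the laws; detection counts
are reported per compound instead.

`N_PR` is a count: integer draws round the continuous sample to the nearest
integer (half-to-even) and clamp into `[max(⌈MIN⌉, 1), ⌊MAX⌋]`
(`tg_sample_integer()`). Whether presentations should be randomized
continuously instead is not decidable from the procedure's description;
both samplers exist and the integer one is the default.

Reproducibility uses one master seed per run; every parameter, compound and
replicate consumes a child seed from a stable string hash
(`child_seed()`), so adding a compound or running IR after HI never
perturbs other streams, and the caller's RNG state is never touched.

## Acceptability and summaries

Each category yields 1000-iteration HI and IR distributions (iteration
count and percentile configurable). Summaries report mean, SD, the
25/50/75/95th percentiles and the maximum, using linear interpolation
between order statistics (R type 7, named in the output metadata).
Acceptability is strict: the scenario passes iff the 95th percentile lies
strictly *below* HI = 1 and IR = 10⁻⁵ — a risk equal to the threshold is
unacceptable. CDF and histogram point series are exported for plotting
(`empirical_cdf()`, `pdf_histogram()`).

## Sensitivity test

Robustness to the single-run randomization is checked by rerunning the
simulation 5 times under independent child seeds and computing all pairwise
two-sample Kolmogorov–Smirnov sup distances between the replicate CDFs
(`run_replicates()`, `sensitivity_report()`). "The CDFs overlap" is a
visual criterion; the numeric operationalization (KS distance with default
tolerance 0.05) is this package's declared convention and is configurable.
At 1000 iterations the null distribution of a single pairwise KS distance
has median ≈ 0.037 and the maximum over the 10 pairs of 5 replicates hovers
around 0.05, so the strict default occasionally flags pure Monte Carlo
noise as instability; 0.10 is comfortably above the noise floor (the test
suite verifies that ≥ 95% of repeated 5-replicate runs stay below 0.10) and
is the tolerance we recommend at this iteration count. Raising iterations
tightens the floor as `1/√n`.

## Synthetic data generator

Real panel surveys are confidential, so validation uses a generator with
known ground truth (`default_scenario()`, `generate_dataset()`). It
emulates the structure of an annual laboratory survey: 13 industrial
categories totalling 1035 olfactometric samples; exactly
`round(0.25 · n)` samples per category chemically characterized (partial
characterization is the norm — chemistry is slow and must happen within the
30-h sample lifetime); log-normal concentrations (right-skewed, mass toward
low values, matching the shape reported for real odor-sample chemistry)
with per-compound detection thinning; log-normal odor concentrations; and a
15-member panel whose `N_Y` and `F_S` are widely dispersed — career lengths
of 1–25 years, 20–700 samples/year — because that heterogeneity is what
motivates a probabilistic treatment in the first place. Two categories
(`wwtp`, `biofuel`) deliberately contain no carcinogen so the
"not computable" path is exercised end to end. All toxicological values in
the generated table are plausible placeholders labelled synthetic; they are
not a regulatory reference.

The generator intentionally commits the same model misspecification the
method itself incurs: data are log-normal, fits are truncated Gaussians.
Passing validation therefore shows the pipeline reproduces its *own* model
faithfully (fit → simulate → closed-form truncated-normal quantiles agree
to within Monte Carlo error), not that a truncated Gaussian is the true law
of any real laboratory — no synthetic test can show that. Features of real
data the generator does not emulate include between-compound correlation
within a sample (the simulator also draws compounds independently, a
documented simplification), seasonal structure, and censoring at analytical
detection limits.

Single-compound scenarios with degenerate (σ = 0) exposure parameters admit
closed-form references: the HI quantile is the truncated-normal quantile of
`Cin` over the OEL, and the IR quantile scales it by `IUR × f`
(`analytic_reference_risk()`). These anchor the acceptance-style tests at
5% relative tolerance with 10⁴ iterations.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation); verdicts strict (`<`).
* σ = 0 specs are point masses; they never crash and collapse every
  simulation to its deterministic value exactly.
* Truncated sampling clamps into `[MIN, MAX]` after the inverse-CDF map; a
  window far in the parent tail degenerates to the nearer bound rather than
  overflowing.
* Unit canonicalization happens exactly once, at ingest, to µg/m³ (the
  IUR's own basis); mg/m³ → µg/m³ is an exact ×1000.
* Compounds missing from the toxicology table are excluded with a logged
  warning and appear exactly once in the exclusion report — never silently
  dropped, never imputed.
* A category whose compounds all lack OELs is skipped with a reason and the
  run continues (partial-failure policy).
* Ties in `N_PR` rounding follow R's half-to-even.

## Problem sizes

Default runs use 1000 Monte Carlo iterations per category and metric, the
resolution at which the 95th percentile of a unimodal risk distribution is
stable to a few percent; validation tests use 10⁴ iterations where they
compare quantiles to closed forms, and the synthetic recovery scenarios use
400-sample categories (200 characterized), enough for the fitted truncated
Gaussian to sit close to its generating statistics.

## Known limitations

The hazard index ignores chemical interactions and toxicokinetic
differences between compounds — it is the standard, deliberately simple and
conservative mixture summary, and nothing more. Minimum-dilution-value
(MDV) approaches from earlier deterministic work are out of scope. The OEL
source hierarchy is the tox-table author's responsibility: when several
authorities publish different limits for one compound, choosing among them
is a policy decision this package does not make.
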