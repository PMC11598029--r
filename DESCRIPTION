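Package: olfrisk
Title: Probabilistic Occupational Risk Assessment for Dynamic Olfactometry Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo estimation of the occupational health risk incurred by
    human assessors (panelists) performing dynamic olfactometry (EN 13725).
    From per-sample chemical concentrations, odor concentrations and a panel
    exposure survey, the package fits truncated Gaussian distributions to every
    exposure input, simulates distributions of the hazard index (HI,
    non-carcinogenic) and the inhalation risk (IR, carcinogenic) per industrial
    sample category, and evaluates acceptability at the 95th percentile
    (HI < 1, IR < 1e-5). Includes olfactometric arithmetic (odor concentration
    from threshold matrices, retrospective panel screening, the conservative
    safety factor k), a replicate sensitivity test based on the
    Kolmogorov-Smirnov distance between empirical CDFs, a synthetic laboratory
    dataset generator with known ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
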