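Package: bpwmh
Title: Midlife Blood Pressure and White Matter Hyperintensity Burden
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for studying the relationship
    between midlife blood pressure (BP) and the severity of white matter
    hyperintensities (WMH) in longitudinal cohorts shaped like the UK
    Biobank imaging substudy. Provides harmonization of multi-source BP
    readings, derivation of logit-transformed WMH load, linear models of
    concurrent and past BP with standardized and per-unit effects,
    population attributable fractions for top-decile WMH load via logistic
    g-computation, a regression-dilution-adjusted "usual BP" stratified
    analysis with non-parametric bootstrap confidence intervals, treatment
    category contrasts, and a synthetic longitudinal cohort generator with
    known ground-truth effects so every stage is testable without
    restricted data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
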