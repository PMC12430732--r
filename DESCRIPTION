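Package: phdcox
Title: Planetary Health Diet Scores, Composite Polygenic Risk, and Cox
    Models for Cancer Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for prospective diet-and-cancer cohort analyses: a
    14-component planetary health diet (PHD) score with adequacy, balanced
    and moderation scoring rules and 2500-kcal energy normalisation;
    per-site additive polygenic risk scores combined into an
    incidence-weighted composite cancer polygenic risk score (CPRS) with
    quintile-based genetic risk groups; an auditable cohort exclusion
    cascade and analysis-dataset assembly; a Cox proportional-hazards
    engine (Efron ties, Newton-Raphson) with Schoenfeld proportional
    hazards diagnostics, restricted cubic spline dose-response models and
    trend tests; and a synthetic cohort generator that emulates a large
    prospective biobank (right-skewed dietary intakes, binomial genotype
    dosages, exponential proportional-hazards event times with
    administrative censoring) so every analysis stage can be exercised and
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite
Config/testthat/edition: 3
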