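Package: phenodelta
Title: Phenotypic Age Scoring and Lifestyle Correlates of Biological Age Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes phenotypic age (PhenoAge) from routine clinical
    biomarkers via a Gompertz mortality-score transform, including the
    six-marker reduction and sex-specific linear mapping used with Taiwan
    Biobank panels, and analyses within-individual change in PhenoAge
    (delta-PhenoAge) against lifestyle factors: partial-correlation
    screening with Fisher-z confidence intervals, exact best-subset
    ordinary least squares minimizing AIC with forced-in predictors,
    variance inflation diagnostics, and a reproducible synthetic cohort
    generator for validating the full two-stage pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
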