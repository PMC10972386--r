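Package: lipicyte
Title: Integrative Lipidomics and Cytokine Analysis for Brain Injury Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for integrating untargeted LC-MS lipidomics
    feature tables with multiplex cytokine panels in case/control injury
    designs. Implements retention-time filtering, sham-anchored batch-effect
    feature removal by Welch's t-test, exact-mass lipid annotation with adduct
    tables and MS2 diagnostic-fragment confirmation, isotope/sibling feature
    summation, ANOVA + Tukey HSD volcano analysis with fold-change
    classification, linear-range cytokine filtering with injury-effect
    modelling, and dual-threshold (fold change x Spearman rho) lipid-cytokine
    integration. Ships a synthetic-data generator with known ground truth
    (planted batch shifts, injury effects, and copula-coupled lipid-cytokine
    pairs) so every stage is testable against a recoverable answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
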