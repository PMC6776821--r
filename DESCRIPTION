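Package: liabkin
Title: Familial Coaggregation, Liability-Threshold Models, and Polygenic
    Scores for Comorbid Binary Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Three genetically informative designs for studying the
    overlap of two binary disorders in population cohorts: familial
    coaggregation odds ratios across relative classes with cluster-robust
    variance; bivariate liability-threshold (ACE/ADE/AE) quantitative
    genetic models for full-sister and maternal half-sister pairs, with
    tetrachoric correlations, AIC model selection, heritability,
    coheritability and genetic correlation; and polygenic risk score
    construction (QC filtering, LD clumping, p-value threshold scoring)
    with clustered linear association tests against symptom scales.
    Includes a synthetic-cohort generator with known genetic architecture
    so every stage is testable without access to register data, and a
    reproduction mode that regenerates published summary results from
    bundled printed counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    numDeriv,
    sandwich,
    stats,
    utils,
    withr
Suggests:
    mvtnorm,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
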