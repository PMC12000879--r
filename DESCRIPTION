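Package: ernscreen
Title: Fitness Scoring and Genetic-Interaction Mapping for Arrayed
    Epigenetic-Regulator Knockout Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for arrayed CRISPR knockout fitness screens of
    chromatin and DNA-methylation regulators. Computes per-gene fitness scores
    normalized to same-plate negative-control wells, classifies gene
    dispensability against the observed control range and a half-maximal
    threshold, detects genetic interactions between a background knockout and
    each target via per-gene offset linear models with Wald tests, and
    summarizes class and paralogue enrichment among calls. Also quantifies
    SILAC-referenced relative abundance of modified histone peptides with
    differential calling, and implements auxiliary screen rules:
    immunofluorescence knockout gating, clone scoring, growth-rate slope
    comparison, and consensus/differential peak filtering. A seeded
    synthetic-data module emulates the plate structure and noise of the assay
    so every stage is testable end to end.
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
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
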