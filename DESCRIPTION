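Package: tissuetalk
Title: Multi-Tissue Proteomic Differential Abundance and Endocrine Cross-Talk Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-tissue label-free proteomics cohorts:
    per-tissue two-group differential abundance statistics with
    Benjamini-Hochberg false-discovery-rate control, directional
    tissue-to-tissue cross-talk scoring from secreted-protein correlation
    counts (QENIE-style), candidate secreted-factor ranking and target-program
    prediction, single-sample gene-set scoring, preranked permutation-based
    enrichment, hypergeometric overrepresentation tests with an explicit
    background, principal component QC, and cross-perturbation concordance
    summaries. Includes a seeded synthetic-cohort generator with planted
    condition effects and endocrine driver-to-module edges for calibration
    and recovery testing, plus a file-to-file pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
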