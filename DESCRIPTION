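Package: nsclcssp
Title: Single-Sample Histology Prediction and Fusion Calling for NSCLC
    Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based single-sample prediction of non-small cell lung
    cancer histology (adenocarcinoma, squamous cell carcinoma, large-cell
    neuroendocrine carcinoma) from an 11-gene marker panel, using binary
    within-sample gene-pair rules fed to a naive Bayes classifier with
    cross-validated rule-count selection. Includes NanoString nCounter
    count handling (RCC parsing, negative-control background correction),
    gene fusion calling from 3'/5' probe imbalance combined with
    fusion-specific junction probes, MET exon 14 skipping detection from
    an exon 13-15 junction probe, an evaluation harness (accuracy,
    balanced accuracy, macro one-vs-rest AUC, iterated stratified
    hold-out), and a negative-binomial synthetic-cohort generator with
    known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    optparse,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
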