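Package: tootree
Title: Hierarchical Tissue-of-Origin Classification for Tumor Molecular Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the tissue of origin of a tumor from bulk
    RNA expression, gene-level somatic variant calls, and patient sex, using
    an ensemble of per-branch softmax classifiers arranged over a rooted
    cancer-category hierarchy. Scores are propagated down the hierarchy so
    that subcategory scores nest inside their parent category score and all
    terminal scores sum to one, which permits thresholded, confidence-adaptive
    calls of variable granularity (including no-call for cancers of unknown
    primary). Includes hierarchical precision/recall evaluation metrics,
    call-threshold calibration against the call-rate/precision trade-off, a
    clinical triage rule engine for discrepancy review, and a synthetic-cohort
    simulator so every stage is testable without access to clinical data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
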