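Package: ovasig
Title: Molecular Subtyping, Signature Scoring and Drug-Synergy Analysis for
    Ovarian Cancer Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the computational core of a
    multi-cohort high-grade serous ovarian cancer (HGSC) analysis:
    single-sample preranked gene set enrichment analysis (GSEA) for
    molecular-subtype classification with a delta-NES ambiguity filter,
    z-score gene-signature scoring with ROC/AUC evaluation, tumor-immune
    marker metrics (MHC-I/PD-L1 ratio, cumulative marker scores, Pearson
    correlation with random-effects meta-analysis), and dose-response
    synergy quantification (four-parameter logistic EC50 fits, combination
    index, coefficient of drug interaction). Ships synthetic-data
    generators so every stage is exercisable without external cohorts.
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
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    fgsea,
    metafor,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
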