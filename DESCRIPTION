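Package: immunometab
Title: Immune-Metabolomic Profiling of Binned 1H NMR Plasma Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style pipeline for baseline immune-metabolomic
    stratification of plasma samples from binned 1H NMR spectra and
    circulating cytokine panels. Provides fixed-width spectral bucketing
    with exclusion regions and total-integral normalization; a supervised
    PCA-canonical-analysis-kNN classifier with leave-one-out and Monte
    Carlo cross-validation and permutation significance testing; loading
    analysis of the first canonical component; univariate biomarker
    screening (Wilcoxon-Mann-Whitney, Benjamini-Hochberg FDR, Cliff's
    delta, AUROC, Youden threshold); two-feature weighted linear fusion
    models and logic-OR classifier combination; demographic comparison
    tests; and a synthetic cohort generator so the full pipeline can be
    exercised and validated without patient data.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
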