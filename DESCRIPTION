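Package: giscar
Title: Genomic Instability Scar Scoring and HRD Assay Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores homologous recombination deficiency (HRD) genomic
    instability from allele-specific copy-number segment profiles with two
    engines: a scar-count engine (LOH + telomeric allelic imbalance +
    large-scale state transitions, SNP-array adapted rules) and a 28-feature
    Genomic Scar model. Combines genomic-instability status with BRCA1/2
    mutation status into an HRD call, and provides the assay-concordance
    statistics used to compare HRD platforms against a reference assay:
    exclusion rules, 2x2 confusion matrices with exact binomial confidence
    intervals, Pearson correlation, ROC/AUC and Youden-index cut-off
    selection. Includes a synthetic cohort generator for allele-specific
    copy-number profiles with planted scar events and for multi-assay call
    tables with controllable misclassification, plus a transcribed 50-sample
    three-assay call table used throughout the examples and tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pROC,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
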