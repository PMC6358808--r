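Package: plsval
Title: Partition-Validated Paired PLS-DA for Matched-Cohort Metabolomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for the statistical analysis of targeted metabolomic
    panels measured on matched case-control cohorts. Implements
    quantitation-limit (LLOQ/ULOQ) filtering of Biocrates-style panels,
    normality-gated paired and unpaired univariate testing with
    Benjamini-Hochberg correction, multilevel (within-pair) NIPALS PCA with
    Hotelling T-squared outlier screening, NIPALS PLS-DA with VIP variable
    importance, and a validation engine that evaluates a discriminant model
    over systematically thinned exhaustive enumerations of pair-level
    train/test partitions, scoring every partition by test-set AUROC and its
    tail probability under the mean (no-information) model. Includes a
    synthetic matched-cohort generator with effect and null modes so the
    whole pipeline can be exercised and calibrated without access to
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse
Config/testthat/edition: 3
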