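Package: metGC
Title: Development and Validation of Genomic Classifiers of Early
    Prostate-Cancer Metastasis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for building and validating a genomic
    classifier of early clinical metastasis after biochemical recurrence
    from case-control expression data. Implements feature reliability
    filtering from technical-replicate variance, principal-component
    batch-effect removal, two-stage feature selection (per-feature t-test
    followed by bootstrapped elastic-net stability selection), random-forest
    assembly with Gini-ranked backward elimination and grid-search tuning,
    clinical-only and integrated logistic models, and an evaluation suite
    (bootstrap AUC, univariable and multivariable odds ratios, Kaplan-Meier
    with log-rank tests, Gleason-by-score reclassification tables, and
    reverse Kaplan-Meier follow-up). A synthetic-cohort generator provides
    desk-scale data with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    glmnet,
    randomForest,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
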