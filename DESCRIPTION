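Package: cspolar
Title: CXCL9:SPP1 Macrophage Polarity Scoring and Radiogenomic Risk Modeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies the CXCL9:SPP1 (CS) polarity of tumor-associated
    macrophages from multi-patient single-cell RNA-seq counts via per-patient
    adjusted mean counts with a cohort scaling factor, and relates the
    resulting per-patient CS ratio to tissue composition (Ro/e enrichment),
    cell-level mutual exclusivity (odds ratio and Fisher's exact test),
    cross-cell-type gene association scans, bulk-cohort stratification, and
    survival. Implements the two-stage RCSP radiogenomic model: a Pearson
    correlation filter and LASSO with leave-one-out cross-validation yield a
    RadScore; Cox-filtered clinical covariates and the RadScore combine into a
    RiskScore with fixed-threshold survival stratification and ROC evaluation.
    Ships a synthetic-cohort generator with planted patient-level polarity so
    every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    survival,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
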