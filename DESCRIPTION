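Package: tumorHet
Title: Two-Stage Polytomous Models for Etiologic Heterogeneity of Tumor
    Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes etiologic heterogeneity of genetic variants
    across breast-tumor subtypes defined by estrogen receptor (ER),
    progesterone receptor (PR), HER2 and histologic grade.  Implements
    two-stage polytomous logistic regression in which subtype-specific
    case-control log odds ratios over the 24-cell marker
    cross-classification are decomposed into marker-specific case-case
    parameters, with an expectation-maximization treatment of tumor
    markers missing at random, mixed-effect global and fixed-effect
    marker-specific heterogeneity score/Wald tests, intrinsic-like
    subtype and grade odds-ratio models, Benjamini-Hochberg FDR
    screening across variants, per-array fixed-effect meta-analysis,
    and clustering of absolute z-statistics.  A calibrated synthetic
    cohort generator with correlated tumor markers, Hardy-Weinberg
    genotypes and configurable missingness supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    nnet,
    vcfR,
    withr
Config/testthat/edition: 3
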