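Package: colliderMR
Title: Collider Bias Correction for Conditional GWAS via Robust
    Multivariable Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Corrects collider bias in conditional genome-wide association
    studies (GWAS) that adjust for one or more heritable covariates. The
    bias slope vector is estimated by robust multivariable Mendelian
    randomization using constrained maximum likelihood (MVMR-cML) with BIC
    selection of the number of invalid instruments, alongside comparator
    estimators (multivariable IVW, Egger, Lasso, median, and the
    Dudbridge/Hedges-Olkin estimator for a single covariate). Per-SNP
    effects are corrected by subtracting the estimated bias with full
    uncertainty propagation and Wald tests, and tools are provided for
    instrument selection, sample-overlap covariance estimation from null
    z-scores, weak-instrument diagnostics, locus counting over linkage
    disequilibrium blocks, leave-one-out sensitivity analysis, and a
    simulation engine for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
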