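Package: metGP
Title: Genomic and Environmental Prediction for Maize Multi-Environment Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end genomic prediction pipeline for maize multi-environment
    trials (MET) combining marker data with growth-stage environmental
    covariates. Implements per-environment phenotypic analysis (hybrid BLUEs
    with outlier screening), SNP quality control with in-silico hybrid
    construction and genomic relationship matrices, weather-station quality
    control with derived daily variables (Baskerville-Emin growing degrees,
    photothermal time, FAO-56 Penman-Monteith reference evapotranspiration),
    a stage-wise environmental covariate matrix, reaction-norm multi-kernel
    Bayesian linear random effects models with Hadamard-product interaction
    kernels fitted by Gibbs sampling, elastic-net and gradient-boosted-tree
    comparators with nested Gaussian-process Bayesian hyperparameter tuning
    and fANOVA hyperparameter importance, four forward cross-validation
    schemes (CV0/CV00 by year or site) with inverse-variance weighted
    predictive ability, and model interpretation via gain importance and
    partial dependence profiles. A synthetic MET generator with known ground
    truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    ranger,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR,
    optparse
Config/testthat/edition: 3
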