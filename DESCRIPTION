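Package: ipwbias
Title: Large-Sample Bias of IPW and AIPW Estimators of Average Causal
    Effects under Model Misspecification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study what inverse probability weighting (IPW) and
    augmented IPW (AIPW) estimators of the average causal effect converge
    to when the propensity-score and outcome-regression working models are
    both misspecified. Provides declarative data-generating designs with
    seeded samplers, quasi-maximum-likelihood probability limits of
    misspecified working models (by population score equations or
    large-sample fits), the simple (Horvitz-Thompson) and normalized
    (Hajek) IPW estimators and a prototypical doubly robust AIPW estimator
    with sandwich and bootstrap standard errors, plug-in large-sample bias
    functionals with arm-wise decompositions and covariance terms,
    necessary and sufficient conditions for ordering the estimators'
    component biases, overlap and covariate-balance diagnostics, and
    replication engines for finite-sample Monte Carlo studies and
    large-sample numerical bias approximations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
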