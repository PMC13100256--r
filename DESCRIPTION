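Package: pacpredict
Title: Association Versus Prediction Analysis of Pulmonary Artery Compliance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing association from prediction when
    evaluating derived right-heart-catheterization hemodynamics, centred on
    pulmonary artery compliance (PAC). Provides derivation of calculated
    hemodynamic variables with physiologic-range quality control and
    2022 ESC/ERS pulmonary hypertension classification; a calibrated
    synthetic cohort generator with RC-time-coupled PAC and PVR and
    Weibull proportional-hazards survival; a from-scratch survival kernel
    (Cox partial-likelihood fitting with Efron or Breslow ties, Harrell's
    concordance index under censoring, linear tail-restricted cubic
    splines, and a scaled-Schoenfeld proportional-hazards diagnostic);
    adjusted spline hazard-ratio curves and subgroup hazard ratios; and
    Monte Carlo cross-validation comparison of full versus handicapped
    Cox models with frequentist and Bayesian
    region-of-practical-equivalence summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
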