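Package: specswarm
Title: Hybrid Swarm-Genetic Wavelength Selection for Vis-NIR Spectral
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Chemometric workflow for predicting food-quality indicators
    (total volatile basic nitrogen, CIELAB colour) from visible/near-infrared
    reflectance spectra. Implements a hybrid particle-swarm/genetic-algorithm
    wavelength selector with chaotic logistic-map initialization, adaptive
    elite/ordinary subpopulations, nonlinear decreasing inertia, and
    Levy-flight-amplified polynomial mutation, together with baseline
    selectors (binary PSO, GA, grey wolf optimizer, competitive adaptive
    reweighted sampling), SPXY calibration/prediction partitioning, spectral
    preprocessing (SNV, MSC, Savitzky-Golay smoothing and derivatives),
    grid-searched gradient-boosted-tree regression, calibration/prediction
    metrics (R2, RMSE, RPD), and interventional TreeSHAP attribution of the
    fitted models. Includes a synthetic Vis-NIR generator with planted
    informative absorption bands for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    mixOmics,
    signal,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
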