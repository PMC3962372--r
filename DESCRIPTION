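Package: fallseg
Title: Pre-Impact Fall Detection from Body-Segment Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the transition from steady walking to a slipping
    perturbation from multi-segment 3D linear accelerations. Provides a
    synthetic gait generator with perturbation-locked transients, segment
    centre-of-mass kinematics and three-point central differentiation,
    FastICA-style independent component analysis with a Total Segment Weight
    informativeness ranking and bilateral subset selection, a three-layer
    tanh neural network trained by resilient backpropagation with early
    stopping, a consecutive-sample detection rule with detection-time
    metrics, and a nested leave-one-out cross-validation pipeline that
    compares segment subsets by paired t-tests and two-way ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
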