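Package: latsem
Title: Longitudinal Anxiety-Test Structural Equation Models for Retest Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinal-data structural equation modeling for the study of retest
    (practice) effects in repeated cognitive ability testing and their relation
    to situational test anxiety. Implements two-stage polychoric/tetrachoric
    moment estimation with sandwich asymptotic covariances, diagonally weighted
    least squares (DWLS) estimation with mean-and-variance adjusted (WLSMV) test
    statistics, robust maximum likelihood for Likert scales, longitudinal
    confirmatory factor models with configural/weak/strong measurement
    invariance, latent neighbor-change growth curves for retest effect sizes,
    anxiety-interference (double loading) models, scaled chi-square difference
    tests for nested models, the sequential interference-reduction testing
    procedure, and a synthetic multi-wave item-response simulator for
    calibration and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
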