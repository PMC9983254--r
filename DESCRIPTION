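Package: jointcal
Title: Calibration Toolkit for Six Degree-of-Freedom Robotic Joint Testing
Version: 0.1.0
Authors@R:
    person("jointcal", "maintainers", email = "maintainers@jointcal.invalid",
           role = c("aut", "cre"))
Description: Tools for calibrating a six degree-of-freedom robotic joint-testing
    platform against an optical motion tracker. Estimates the optical-to-robot
    coordinate transformation by zeroed least squares, fits the joint rotation
    centre (robot tool centre point) and tool length by algebraic sphere fitting
    with combinatorial four-point solves and iterative sigma-threshold outlier
    rejection, transforms manually recorded joint trajectories into robot world
    coordinates, and summarises reproduction accuracy with the field's table
    conventions (population standard deviation, even-n median deviation, signed
    extreme deviations). Includes a seeded synthetic-data generator emulating the
    physical rig and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
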