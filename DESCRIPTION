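Package: plaquemech
Title: Inverse Finite-Element Characterization of Atherosclerotic Plaque
    Stiffness from Ultrasound Inflation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hybrid experimental-numerical workflow for estimating the shear
    moduli of the arterial wall and the diseased intima of atherosclerotic
    plaques from ex vivo inflation tests imaged with high-frequency ultrasound.
    Provides a synthetic plaque phantom generator (layered cross-section
    contours, calcifications, ultrasound scatterer fields), a plane-strain
    incompressible Neo-Hookean finite-element forward solver with follower
    pressure loading, a linear-array radiofrequency (RF) speckle simulator,
    a three-iteration coarse-to-fine RF cross-correlation displacement
    tracker with parabolic subsample interpolation, thin-plate-spline
    contour registration of histology onto ultrasound, and an inverse
    grid-search engine that fits per-pressure-step shear moduli by
    minimizing the mismatch between computed and measured grid-averaged
    axial displacements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
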