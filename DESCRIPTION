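Package: vesselmech
Title: Finite-Element Mechanopropagation Analysis of Bone-Marrow Blood Vessels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational biomechanics of force transmission along bone-marrow
    vasculature. Generates synthetic tetrahedral vessel meshes (arteriole, artery,
    sinusoid embedded in marrow), models vessel walls with a 5-parameter
    Mooney-Rivlin hyperelastic law and marrow/blood as linear-elastic solids, and
    solves intravascular pulse-pressure inflation, cortical-bone bending and
    vibratory end-stretch load cases with a total-Lagrangian static solver and an
    explicit central-difference dynamic solver. Post-processing reproduces surface
    von Mises stress grids, Gaussian-fitted histograms, threshold area fractions
    and stress-front propagation velocities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
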