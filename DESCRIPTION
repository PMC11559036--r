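Package: mxnfb
Title: Cell Arrangement and Strain Dynamics in Myxococcus xanthus Nascent
    Fruiting Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the three-dimensional arrangement and developmental
    fate of fluorescently labeled Myxococcus xanthus cells in two-channel
    confocal image stacks of nascent fruiting bodies (NFBs). Provides a
    synthetic scene generator with known ground truth (spherocylinder rods,
    transitioning cells, and spherical spores placed with radial density and
    tangential orientation fields, rendered through a Gaussian point-spread
    function with shot and read noise), Hessian-eigenvalue cell enhancement
    with center-quarter Otsu thresholding and 3D segmentation, Gaussian
    mixture classification of cells into rods, transitioning cells, and
    spores, radial statistics (cell density per 1,000 cubic micrometers with
    labeled-fraction correction, Gaussian-kernel neighbor alignment of rods,
    tangential orientation), and Bayesian estimation of strain ratios and
    per-interval sporulation and disappearance rates with 90% credible
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    mclust,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
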