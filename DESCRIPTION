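Package: lsquant
Title: Quantitative Image Analysis for Light-Sheet Microscopy of Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of three-dimensional light-sheet
    fluorescence microscopy stacks of organoids and calibration beads:
    stack pre-processing (cropping, rolling-ball background subtraction,
    axial rescaling to isotropic voxels, rotational maximum-intensity
    projections), 3D nuclei segmentation by local-mean thresholding,
    multiscale Laplacian-of-Gaussian seed detection and marker-controlled
    immersion watershed, alpha-shape and cell-graph morphometry of nucleus
    centroids, bead-based point-spread-function FWHM measurement, and a
    planar-slab refraction model of the focal shift introduced by thin
    container walls. Includes generators for bead and hollow-monolayer
    organoid phantoms with ground truth so every stage can be validated
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
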