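Package: mgca
Title: Multi-Gradient Cellular Automata for Spectral Image Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Segmentation of multiband (RGB to hyperspectral) images with a
    multi-gradient cellular automaton (MGCA) that homogenizes pixel spectra
    using rotation- and reflection-invariant spectral-angle gradients at
    three spatial scales. Transition-rule tables are evolved with
    differential evolution against an intra-/inter-class segmentation cost
    computed on synthetic labeled scenes, so segmenters can be trained on
    cheap low-dimensional synthetic images and applied to cubes with any
    number of bands. Includes a parametric generator of labeled training
    scenes, a pluggable pixel-wise classification stage (support vector
    machine or spectral-angle nearest centroid) and standard map-accuracy
    metrics (overall accuracy, average accuracy, Cohen's kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
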