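Package: ois2d
Title: Two-Dimensional Optical Imaging Spectroscopy of Cortical Hemodynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for two-dimensional optical imaging
    spectroscopy (2D-OIS) of the cortical surface. Converts multispectral
    remitted-light image stacks into oxy-, deoxy- and total hemoglobin
    concentration movies via a modified Beer-Lambert inversion with
    Monte-Carlo estimated photon path lengths, selects stimulus-activated
    regions of interest, separates arterial and venous compartments by
    principal component analysis, and quantifies evoked and gas-challenge
    responses with mixed repeated-measures ANOVA and t-test stages. A fully
    synthetic phantom forward model generates seeded imaging sessions with
    known ground truth, including chronic and acute (cortical spreading
    depression perturbed) scenarios for wild-type-like and Alzheimer-like
    groups, so every pipeline stage can be validated against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
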