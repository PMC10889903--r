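Package: gratingprobe
Title: Probing Tilt Illusions in Convolutional Networks with Oblique Grating Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Synthesis and analysis pipeline for Skye's Oblique Grating, a
    Cafe-Wall-family tilt illusion in which physically horizontal colored bars
    decorated with alternating black and white diamonds appear tilted. The
    package renders the full stimulus grid (12 hues x 6 diamond widths x 2
    positional settings) together with angle-matched tilted counterparts,
    simulates method-of-adjustment perceptual data with the reported hue and
    width structure, scores illusion strength (mean absolute adjusted angle,
    eight 0.1-degree levels, a 0.4-degree no-illusion / with-illusion split),
    trains a compact convolutional classifier to separate tilted from
    near-horizontal renders, and probes the trained network on physically
    horizontal illusion images. Network characterisation includes permutation
    tests of classifier significance, Grad-CAM class activation maps, and
    layerwise cross-set representational dissimilarity matrices with
    mean-normalised L2 distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
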