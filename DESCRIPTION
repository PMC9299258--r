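Package: rdssd
Title: Multimodal RGB-D Single-Shot Detection of Greenhouse Tomato Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual-branch single-shot multibox detection (SSD) over registered
    colour and depth image pairs, for locating greenhouse tomato fruit and
    classifying maturity (green, orange, red) crossed with occlusion state.
    Provides prior-box (anchor) geometry with decision-level fusion of the
    colour and depth branches, IoU matching, non-maximum suppression and the
    multibox objective; an eight-stage paired RGB-D augmentation pipeline; a
    recurrent-attention generative adversarial network for specular highlight
    removal; VOC-style average-precision evaluation with maturity and
    occlusion grouping; and a seeded synthetic Kinect-style RGB-D scene
    generator used throughout the test-suite. All network computation runs on
    a small built-in convolutional engine (im2col plus GEMM via
    'RcppArmadillo') with analytic gradients and Adam optimisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    xml2,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
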