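Package: vesselnet
Title: Dual-Attention Multiscale Feature Fusion Network for Retinal Vessel
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patch-based convolutional segmentation of retinal blood vessels
    in fundus photographs using a dual-attention multiscale feature-fusion
    residual network.  Implements Shuffle Attention (grouped channel and
    spatial gating), Efficient Channel Attention (adaptive-kernel
    cross-channel gating), an attention-gated residual unit, and a two-branch
    fusion backbone with named intermediate tap points.  Includes a seeded
    vascular-phantom generator, 64x64 patch extraction with augmentation,
    tiled overlap-averaged inference, accuracy/sensitivity/specificity
    evaluation, and a full CPU training loop (Adam, exponentially decayed
    learning rate) built on an im2col/GEMM convolution engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff,
    jpeg,
    optparse,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
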