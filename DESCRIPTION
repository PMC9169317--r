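Package: dnlseg
Title: Deformed Non-Local Networks for Blood Vessel Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encoder-decoder semantic segmentation of curvilinear blood
    vessels in 2D medical images (CT angiography slices, retinal fundus
    patches) built around a deformed non-local (DNL) attention block that
    replaces quadratic positional self-attention with channel-similarity
    attention plus a squeeze-and-excitation gate, a channel-attention-guided
    multi-scale feature fusion (MFF) decoder, and a residual
    squeeze-and-excitation pyramid pooling (RSEP) bottleneck. Includes a
    native reverse-mode automatic-differentiation engine with compiled
    convolution kernels, Dice plus weighted cross-entropy training with a
    polynomial learning-rate schedule, pixel-classification metrics
    (Dice, mean IoU, sensitivity, specificity, accuracy, ROC AUC),
    connected-component post-processing, and a seeded generator of
    curvilinear vessel phantoms so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
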