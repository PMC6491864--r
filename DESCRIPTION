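Package: ddunet
Title: Dilated Dense U-Nets for Multi-Class 3D MRI Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based volumetric segmentation of brain MRI with a family of
    3D fully convolutional networks: a 3D U-net baseline, a dilated dense U-net
    (DUnet) that routes the middle skip connection through a dilated dense
    block, and its residual variant (ResDUnet). Includes the complete pipeline:
    bounding-box cropping, histogram matching and flip augmentation,
    foreground-constrained patch sampling, Adam training with a stepped
    learning-rate schedule, overlapped sliding-window inference with
    majority-vote fusion, connected-component false-positive removal, and
    Dice / average symmetric surface distance evaluation. A deterministic
    two-modality phantom generator makes every stage testable end to end
    without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
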