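Package: wranet
Title: Wide Receptive Field Attention Network for Motion Deblurring of
    Crop and Weed Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restoration of motion-blurred crop and weed imagery with a wide
    receptive field attention network (WRA-Net) followed by three-class
    semantic segmentation (background/crop/weed) with a U-Net. Provides the
    encoder-decoder restoration model built from depthwise-separable
    multi-receptive-field blocks, pointwise attention gates, learnable skip
    connections and modulated deformable convolution; a composite SSIM + L1
    restoration loss and Dice segmentation loss; PSNR/SSIM/IOU evaluation
    metrics; a two-stage train-restorer-then-segmenter scheme with cosine
    learning-rate annealing; patch-based tiled inference for large images;
    and a synthetic generator of nonlinear camera-shake blur kernels and
    crop/weed field scenes so the whole system is buildable and testable
    without external datasets. All tensor operations run on a small built-in
    reverse-mode autodifferentiation tape with compiled kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    yaml
Config/testthat/edition: 3
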