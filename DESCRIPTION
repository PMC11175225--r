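Package: rdagan
Title: Residual Dense Attention GAN for Microscopy Image Super-Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-image x2 super-resolution for bright-field microscopy built
    around a residual dense attention generator: densely connected convolution
    blocks with local feature fusion, channel and spatial attention (CBAM),
    global feature fusion, and sub-pixel upsampling, trained adversarially
    against an image discriminator and a VGG-feature discriminator with a
    perceptual plus adversarial composite loss. Includes a paired HR/LR data
    pipeline with bicubic degradation, cropping and dihedral augmentation, a
    synthetic bright-field cell-scene generator for offline fixtures,
    Y-channel PSNR/SSIM evaluation in BT.601 YCbCr space, and a minimal
    reverse-mode automatic-differentiation engine with Rcpp convolution
    kernels so the whole method runs without an external deep-learning
    framework.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
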