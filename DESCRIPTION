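Package: lfeunet
Title: Lightweight Full-Encoder U-Shaped Networks for Medical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, trains and evaluates lightweight full-encoder U-shaped
    convolutional networks (LFE-UNet) for 2D semantic segmentation of medical
    images. Every decoder layer aggregates resampled feature maps from all
    encoder levels, so a very small channel budget (8 base channels) suffices.
    Includes closed-form and empirical trainable-parameter accounting for the
    Vgg-style and ResNet34-style backbones, nine segmentation losses (cross
    entropy, L2, soft F1, binary cross entropy with and without logits, Dice,
    Tversky, focal, Kullback-Leibler) and weighted combinations such as DFK,
    Gaussian image-noise and salt-and-pepper label-noise injection for
    robustness studies, nested brain-tumor sub-region (WT/TC/ET) Dice
    evaluation, seeded synthetic liver-like and brain-tumor-like dataset
    generators, PNG/NIfTI dataset input and output, and a CPU training engine
    (Adam, reduce-on-plateau schedule) written with RcppArmadillo kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    RNifti,
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
NeedsCompilation: yes
RoxygenNote: 7.3.3
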