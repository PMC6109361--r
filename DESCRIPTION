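Package: mfcnsr
Title: Multi-Scale Fusion Convolutional Networks for MR Image
    Super-Resolution
Version: 0.1.0
Authors@R:
    person("MFCN-SR", "Developers", email = "mfcnsr@example.org",
           role = c("aut", "cre"))
Description: Single-image super-resolution of structural brain MR volumes
    with small multi-scale fusion convolutional networks (MFCNs). Provides
    a synthetic brain-phantom generator, the blur/downsample/bicubic
    degradation model with masked 33x33 patch-pair extraction, declarative
    construction and CPU training (Euclidean loss, SGD with momentum) of
    MFCNs and their plain stacked-CNN counterparts, masked image-quality
    metrics (RMSE, SNR, PSNR, SSIM), architecture-ablation harnesses, and
    a subcommand command-line interface with minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
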