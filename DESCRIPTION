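Package: sdresnet
Title: Scanning-Radius Artifact Correction for Circular-Scan
    Photoacoustic Tomography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates ring-array photoacoustic acquisitions with a
    k-space pseudospectral wave solver, reconstructs initial-pressure
    images by delay-and-sum (DAS) beamforming under deliberately biased
    scanning radii, and trains a smooth-deconvolution residual
    encoder-decoder network (SD-ResNet) that maps artifact-contaminated
    reconstructions back to ground-truth-quality images.  Includes
    synthetic phantom generation, paired dataset construction with
    percentile normalization and augmentation, image-quality metrics
    (PSNR, SSIM, MSE, PCC), dB-compressed visualization, and
    command-line entry points for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
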