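Package: hwdenoise
Title: Hybrid Wavelet-Autoencoder Denoising for Medical Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoising of grayscale medical images (ultrasound, MRI, X-ray) by
    a hybrid pipeline that combines multi-level wavelet shrinkage over five
    wavelet families with a patch-based convolutional autoencoder, fused by a
    learned two-channel convolutional network. Includes simulators for
    Gaussian, speckle, Rician and Poisson noise, deterministic synthetic
    phantoms, full-reference quality metrics (PSNR, SSIM), an adaptive Wiener
    baseline, and an ablation/evaluation harness, so the complete pipeline can
    be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
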