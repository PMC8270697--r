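Package: virtstain
Title: Two-Stage Generative Adversarial Virtual Histological Staining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for weakly supervised virtual H&E staining of tissue
    microscopy tiles. Stage one learns an unpaired translation from stained
    histology tiles to pseudo-autofluorescence ("unstained") tiles using a
    cycle-consistent adversarial model extended with a two-input
    domain-consistency discriminator, per-domain input buffers of heavily
    augmented real tiles, and a depthwise-separable generator. Stage two trains
    a paired stain-transfer generator (a parallel feature fusion network built
    from multi-scale UNet extractors) with Wasserstein-gradient-penalty,
    pixel-L1 and feature-matching objectives. Includes a synthetic-histology
    tile simulator, image-quality metrics (Frechet distance, Inception Score,
    Mode Score), a classifier-based visual evaluation harness, and a small
    CPU convolutional-network engine with reverse-mode gradients that the
    architectures are built on.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
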