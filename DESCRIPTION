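Package: voxsynth
Title: Patch-Based 3D Conditional GAN Synthesis of CT-Like Volumes from MR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for translating one volumetric imaging modality into
    another with a patch-based 3D conditional generative adversarial
    network (pix2pix). Implements the full pipeline: NIfTI volume I/O,
    field-of-view harmonisation and cubic-spline resampling of paired
    volumes, two-stage intensity normalisation onto [-1, 1], overlapping
    patch decomposition with overlap-aware merging, a cyclic rotation
    augmentation schedule, 3D U-Net generators and PatchGAN
    discriminators trained with the cGAN + L1 objective, multi-kernel
    model ensembling with range alignment, and a quantitative similarity
    suite (cosine angle distance, Euclidean distance, MSE, PSNR, MSSIM).
    A synthetic paired head-phantom generator with a known source-to-target
    mapping provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tibble,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
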