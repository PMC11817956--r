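Package: neuroseg
Title: Small Brain Tumor Segmentation and Detection Feasibility Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, fully tested pipeline for studying the feasibility of
    segmenting and detecting small metastatic brain tumors in 3D MRI with very
    small labeled datasets. Provides a synthetic brain-phantom generator that
    emulates clinical T2-FLAIR series (DICOM-style grayscale metadata, polygon
    annotations, white-matter-hyperintensity confounders), the DICOM grayscale
    standardization chain (modality, value-of-interest and presentation
    look-up tables), slice decimation/interpolation/padding to canonical
    128x128x64 volumes, geometric data augmentation, scale-configurable 3D
    U-net and Swin-transformer segmentation networks with manual
    backpropagation, cutout-based contrastive self-supervised pretraining,
    transfer-learning strategies with layer freezing, cross-validation
    orchestration, and Dice/detection evaluation including the small-lesion
    Dice size-bias analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    jsonlite,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
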