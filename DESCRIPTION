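Package: projage
Title: Brain Age Regression from 2D Moment Projections of 3D MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts brain age from 3D structural MRI by compressing each
    volume into a handful of 2D moment images (per-pixel mean and standard
    deviation across axial, coronal and sagittal slices) and training a
    three-stream 2D convolutional regression network on them. Provides an
    aging-brain phantom simulator so the whole pipeline is exercisable
    without restricted data, NIfTI volume handling with symmetric
    zero-padding, offline affine plus elastic augmentation, a compact
    convolutional training engine with Adam and best-validation
    checkpointing, accuracy metrics, and a channel-ablation study with
    per-channel marginal contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
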