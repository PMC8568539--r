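Package: rdaunet
Title: Residual Dual-Attention U-Net for Kidney Segmentation in Abdominal CT
Version: 0.1.0
Authors@R: person("rdaunet", "maintainers", email = "rdaunet@example.org", role = c("aut", "cre"))
Description: Segmentation of kidneys (including renal cysts) in abdominal CT
    slices with a residual dual-attention U-shaped convolutional network,
    trained with Dice loss. Provides a synthetic abdominal-CT phantom
    generator with exact ground-truth masks and analytically known kidney
    volumes, Hounsfield-unit windowing and preprocessing, left/right kidney
    evaluation metrics (Dice similarity, precision, recall) split at the
    spine, total-kidney-volume (TKV) estimation from stacked slice masks,
    minimal DICOM and NIfTI-1 input/output, and a command-line interface.
    All network forward and backward passes are implemented in the package
    (RcppArmadillo); no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
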