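Package: bmseg
Title: Detection and Segmentation of Small Brain Metastases with a 2.5D
    Overlapping-Patch U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for lesion-level detection and voxel-level
    segmentation of small brain metastases on contrast-enhanced T1 MR volumes.
    Implements 2.5D overlapping-patch preprocessing (five consecutive axial
    slices as network input channels, 128x128 patches at 64-pixel stride),
    class-balanced patch sampling, a trainable 2D U-Net with ELU activations
    and batch normalization built on fast C++ convolution kernels,
    probability-averaged patch merging, minimum-volume lesion rejection, and
    lesion-level evaluation metrics (sensitivity, false positives per patient,
    Dice, Dice with 3 mm dilation, 95th-percentile Hausdorff distance).
    Includes a synthetic head-phantom generator producing paired images and
    ground-truth masks so every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
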