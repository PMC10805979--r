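Package: AdenoVol
Title: Automated Volumetric Assessment of Pituitary Adenoma from MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated volumetry pipeline for pituitary adenoma on
    T1-weighted contrast-enhanced MRI. Volumes are conformed to a canonical
    grid (right-anterior-superior orientation, isotropic spacing, fixed
    shape, per-study intensity normalization), segmented slice-wise in the
    coronal plane by an ensemble of 2D U-Net convolutional networks trained
    in k-fold cross-validation, and postoperative masks are cleaned by
    morphological postprocessing. From pre- and postoperative masks the
    package computes tumor volumes in cubic millimetres, extent of
    resection, gross-total-resection classification with confusion
    statistics, and segmentation-quality metrics (Dice, Jaccard, 95th
    percentile Hausdorff distance). A seeded synthetic phantom generator
    produces pre/postoperative study pairs with analytic ground truth for
    end-to-end validation. The U-Net (convolution, pooling and upsampling
    layers, binary cross-entropy loss, Adam optimizer, backpropagation) is
    implemented in compiled code within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
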