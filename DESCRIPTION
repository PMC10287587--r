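Package: slseg
Title: Super Learner Ensemble Segmentation of Lipomatous Tumors in MR Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ensemble framework for semantic segmentation of lipomatous
    tumors in heterogeneous multicenter MR images. Provides MR volume and
    mask handling (NIfTI and raw float32 cache), grid resampling, bias-field
    correction and four intensity normalization/standardization methods
    (z-score, volume and slice min-max, Nyul histogram standardization),
    2D U-Net and attention U-Net base learners trained with a dice loss under
    K-fold cross-validation, simplex-constrained Super Learner weight
    optimization that combines per-voxel probability maps, overlap- and
    boundary-based evaluation metrics (DSC, sensitivity, specificity, HD95,
    voxelwise ROC/AUC), and a seeded synthetic phantom generator emulating
    multicenter intensity heterogeneity for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
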