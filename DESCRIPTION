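Package: radstab
Title: Inter-Observer Stability Analysis of Radiomic Features for
    Pulmonary Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how inter-observer variation in lesion
    segmentation propagates into radiomic features. Provides a synthetic
    pulmonary-nodule phantom generator with simulated observer
    segmentations, a from-scratch 1,246-feature radiomic catalogue
    (first-order, 3D shape, GLCM, GLRLM, GLSZM and GLDM texture families
    on the original image plus Laplacian-of-Gaussian and stationary
    3D-wavelet filtered images), and multi-rater agreement statistics
    (Dice overlap, Lin's concordance correlation coefficient, the overall
    concordance correlation coefficient, and the intraclass correlation
    coefficient), together with a study pipeline that classifies feature
    stability and summarises it by feature class, image type and nodule
    density class.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
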