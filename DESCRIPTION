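Package: pupaevision
Title: Species and Sex Identification of Silkworm Pupae from Images
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based identification of silkworm (Bombyx mori) pupa
    species and sex for sericulture breeding. Provides a synthetic
    labeled pupa-image generator with ground-truth contours, segmentation
    and standardized cropping, a 37-dimensional pupal shape descriptor
    built around a 23-point curvature-width profile with head/tail
    canonicalization, classical texture and color descriptors (HOG, Hu
    moments, uniform LBP, GLCM, HSV histograms) at fixed output
    dimensions, a CNN feature stage with a reproducible training
    protocol, weight-stratified data partitioning, PCA-type descriptor
    fusion, grid-searched shallow classifiers (MLP, one-vs-rest SVM,
    random forest), and macro-averaged evaluation with one-vs-rest
    precision-recall and ROC curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    randomForest,
    withr,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
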