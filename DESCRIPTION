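Package: calcseg
Title: Segmentation and Quantitative Analysis of Breast Calcification in
    Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for mammographic calcification analysis:
    generation of phantom mammograms with known ground truth, overlapping-tile
    decomposition of large images, calcification-tailored data augmentation
    (including connected-component copy-paste), a lightweight encoder-decoder
    segmentation network built from convolutional, fused-MBConv and
    tokenized-MLP blocks trained with a two-phase focal/Dice then
    Hausdorff-distance loss schedule, pixel-level segmentation metrics with
    bootstrap confidence intervals, morphological feature quantification of
    segmented lesions (shape, density, dilation-based cluster statistics), and
    benign/malignant classification of the resulting feature tables with seven
    standard machine-learning algorithms.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    EBImage,
    png,
    tiff,
    rpart,
    randomForest,
    e1071,
    class,
    xgboost,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
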