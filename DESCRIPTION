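Package: boxsig
Title: Detection-Box Radiomics Signatures for Ultrasound Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for studying whether
    radiomics signatures extracted from lesion detection bounding boxes can
    replace signatures extracted from manual segmentations in ultrasound
    breast-lesion classification. Provides a speckle-phantom generator with
    ground-truth masks, boxes and simulated annotators; annotation-aware
    geometric and filter-based image augmentation; a trainable HOG-plus-cascade
    sliding-window lesion detector and a reader for external detections; a
    joint IoU / localization-error detection evaluation framework with
    recall-threshold curves; native 2D radiomics feature extraction (first
    order, GLCM, GLRLM, GLSZM, GLDM, NGTDM over filtered image derivatives);
    LASSO signature selection with cross-validated penalty search; and
    KNN-family classifiers evaluated with ROC/AUROC and DeLong's test for
    correlated AUCs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    glmnet,
    jsonlite,
    xml2,
    png,
    withr,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
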