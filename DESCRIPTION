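Package: cytogan
Title: Two-Step Training of Cytology Patch Classifiers with Progressively
    Grown GANs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for benign/malignant classification of lung cytology
    patch images with limited labeled data. Tiles microscopy fields into
    non-overlapping 256x256 patches, applies an expert patch-selection
    table, augments by rotation/flip/color-gain and focus-variation
    filters, synthesizes additional training images per class with a
    progressively grown Wasserstein GAN (plus a DCGAN baseline and a
    sliced Wasserstein distance quality metric), pretrains a VGG-style
    convolutional classifier on the synthetic images, fine-tunes only its
    fully connected head on real patches, and evaluates with confusion
    matrices, sensitivity/specificity, ROC curves and AUC under a
    holdout-plus-threefold cross-validation protocol. Includes a seeded
    synthetic cytology image generator so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
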