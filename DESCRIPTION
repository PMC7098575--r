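Package: gximage
Title: Gene-Expression Images and Transfer Learning for Fixed-Time
    Survival Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms RNA-seq gene-expression vectors into two-dimensional
    "gene-expression images" by laying out a KEGG BRITE functional-hierarchy
    tree with an ordered (pivot-by-size) treemap, so that convolutional neural
    networks can exploit local expression motifs. Provides the full modelling
    pipeline around the image transform: unsupervised gene filtering (constant
    removal, top-k median absolute deviation), fixed-time binarization of
    right-censored progression-free-interval outcomes, class-imbalance handling
    (random oversampling, SMOTE), a pre-train/fine-tune transfer-learning
    scheme with CNN and multi-layer neural-network models written in native R,
    repeated stratified cross-validation with ROC-threshold metrics, classical
    machine-learning baselines, paired Wilcoxon model comparison with Hochberg
    correction, and a synthetic-data generator with hierarchy-localized outcome
    signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    Matrix,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    kernlab,
    nnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
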