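Package: stagernet
Title: Embryo Stage Classification from Small Microscopy Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training accurate two-class image-stage classifiers from
    small microscopy datasets. Implements a biologically informed data
    augmentation toolbox (rotation with canvas enlargement, shear, crop,
    Gaussian blur, cutout, horizontal flips and Moebius conformal warps),
    leakage-safe stratified cross-validation over source images, a bespoke
    VGG-block-style convolutional network with exact shape inference and
    layer freezing for fine-tuning, an early-stopping training regime with
    best-weight restoration, SmoothGrad saliency maps with landmark-aligned
    class means and region scoring, traditional baselines (Haralick texture
    features, PCA + k-means, random forest / SVM / k-nearest-neighbour), and
    a seeded synthetic embryo-image generator so the whole pipeline is
    testable end to end without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    class,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
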