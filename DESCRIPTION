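Package: DRENet
Title: Dense Residual Ensemble Networks for Shoulder Implant Radiographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classification of shoulder implant manufacturers from plain
    radiographs with a dense residual ensemble network (DRE-Net): a modified
    ResNet-50 and a modified DenseNet-201 truncated at global average pooling,
    whose 2048- and 1920-dimensional feature vectors are concatenated and
    classified by a shallow concatenation network. Includes rotational
    invariant augmentation (36 in-plane poses per training image), stratified
    10-fold closed-world evaluation with macro metrics, open-world
    identification of unseen manufacturers by nearest-class-mean matching of
    concatenation-layer features, a PCA plus k-nearest-neighbour feature
    baseline, and a deterministic synthetic implant phantom generator so the
    whole pipeline is testable without any external image data. The
    convolutional forward and backward passes run on a compact single-precision
    engine written with RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
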