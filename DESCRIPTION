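Package: frbain
Title: Fuzzy Radial Basis Adaptive Inference Networks for Multichannel
    Time-Varying Signal Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of multichannel time-varying signals (such as
    multi-lead ECG heartbeats) with fuzzy radial basis adaptive inference
    networks. Signal similarity is measured by multivariate dynamic time
    warping; kernel-center prototypes are selected per pattern class by fuzzy
    c-medoids clustering over the warping-distance matrix with a validity-index
    scan of the cluster count; the network combines a fuzzy radial basis
    membership layer, per-class pattern pooling, product-rule fuzzy inference
    and a trainable Takagi-Sugeno classifier head learned by Adam gradient
    descent. Includes a synthetic generator of warped, noisy, imbalanced
    class/subclass signal datasets and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
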