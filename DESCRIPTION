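Package: lesionlab
Title: Hybrid Radiomic and Deep-Feature Analysis of Dermoscopic Skin Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete, testable pipeline for dermoscopic skin-lesion
    analysis: image enhancement (mean plus Laplacian sharpening) and
    DullRazor-style hair removal, leakage-safe stratified splitting with
    class-specific augmentation planning, marker-controlled watershed
    segmentation of the lesion region of interest, handcrafted radiomic
    feature extraction (gray-level size-zone and dependence matrices,
    color histograms, local binary patterns; 96 features), pluggable deep
    convolutional feature extraction via global average pooling, z-score
    feature fusion, artificial neural network, support vector machine and
    random forest classifiers, and a one-vs-rest evaluation suite with
    dual AUC estimators. Ships a synthetic dermoscopy image generator so
    every stage is exercisable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    ranger,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
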