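Package: painface
Title: Objective Pain Grading for Mouse Facial Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for objective, video-based grading of trigeminal pain in
    head-fixed mice. Implements a two-channel neural classifier: a score-map
    keypoint network that localises eight pupil and forelimb landmarks via
    deconvolutional heatmap heads, and a six-layer 3-D convolutional network
    that encodes facial texture over short clips; the two channels are fused
    by freezing the trained keypoint network and training a joint softmax
    head over the concatenated 32-dimensional feature vector. Also provides
    the supporting assay machinery: delta-F-over-F extraction of infraorbital
    nerve fluorescence with ring-contamination subtraction, the up-and-down
    von Frey filament threshold procedure, an image preprocessing pipeline
    (face crop, resize, blur rejection, clip assembly, class balancing), a
    synthetic mouse-face video generator for end-to-end testing, and
    classification metrics (macro precision, recall, F1, one-vs-rest AUC).
    All network layers (2-D/3-D convolution, transposed convolution, max
    pooling) and the SGD training loops are implemented in the package with
    fast C++ kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
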