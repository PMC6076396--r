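Package: phenoseq
Title: Temporal Phenotype Classification of Rosette Growth Image Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies top-view rosette plant time-lapse sequences into
    genotype (accession) classes. Provides a synthetic rosette time-lapse
    generator with ground-truth masks; plant segmentation by per-channel Otsu
    thresholding in L*a*b* colour space, trinary-mask combination and GrabCut
    refinement; hand-crafted colour, shape, Fourier-contour and grey-level
    co-occurrence descriptors; a small convolutional network trained on
    area-split sub-classes with rotation augmentation exposing penultimate-layer
    deep features; recurrent (RNN/LSTM) sequence classifiers built from first
    principles; and SVM and linear-chain CRF baselines, with a pipeline that
    runs and evaluates all five model variants on plant-level splits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    EBImage,
    igraph,
    e1071,
    png,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
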