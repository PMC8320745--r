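Package: medmat
Title: Learning Material Categories and Machine-Discovered Attributes from
    Radiography-Style Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end system for material analysis of grayscale
    radiography-style images. Builds labeled 32x32 texture patch datasets from
    annotated images using brightness and mask-tolerance rules; trains a
    Siamese similarity network whose aggregated same/different decisions yield
    a perceptual distance matrix between material categories; optimizes a
    category-attribute probability matrix that embeds those distances while
    pulling entries toward an arcsine Beta(0.5, 0.5) prior via a Gaussian
    kernel density estimate and Kullback-Leibler divergence; and trains a
    multi-task convolutional classifier with auxiliary attribute heads that
    predicts categories and attributes per patch and in sliding-window fashion
    over whole images. Includes a deterministic synthetic radiography scene
    generator so the whole pipeline is testable without medical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Rcpp,
    EBImage,
    png,
    jsonlite,
    cluster
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'attributes.R'
    'nn-ops.R'
    'dcnn.R'
    'distance.R'
    'maccnn.R'
    'inference.R'
    'medmat-package.R'
    'patches.R'
    'synthetic.R'
    'study.R'
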