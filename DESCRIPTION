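Package: sharedrep
Title: Information-Theoretic Analysis of Shared Representations in Bimodal Autoencoders
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how modality-invariant ("shared") categorical
    representations form in the hidden layers of bimodal autoencoders.
    Provides a synthetic paired two-modality digit dataset generator,
    construction of consistent and inconsistent visual/auditory training sets
    with modality-dropout augmentation, dense bimodal autoencoders in the
    mixed-input and two-stage frameworks trained with AdaDelta and binary
    cross-entropy, binned stimulus-specific single-cell information analysis
    of hidden units, a four-way unit selectivity typology with
    percentile-based thresholds, frozen-encoder cross-modal transfer
    evaluation with a supervised softmax head, and replicate-level experiment
    orchestration with standard statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    SummarizedExperiment
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, NeuralNetwork
RoxygenNote: 7.3.3
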