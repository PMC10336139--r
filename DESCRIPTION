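Package: codal
Title: Disentangled Topic Models for Multi-Batch Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variational topic models for multi-batch single-cell RNA-seq and
    ATAC-seq that separate biological expression or accessibility rates from
    batch-driven technical effects by penalizing the mutual information between
    the two with a spectrally normalized neural critic. Includes amortized
    variational inference with cyclically annealed training, a pruning-aware
    Bayesian hyperparameter tuner with a Gaussian-process surrogate, technical-
    effect-augmented regulatory-potential models linking chromatin accessibility
    to expression with probabilistic in-silico deletion, and a synthetic
    generator of batch-confounded differentiation trajectories for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    methods,
    mclust,
    generics,
    tibble,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    hdf5r,
    knitr
Config/testthat/edition: 3
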