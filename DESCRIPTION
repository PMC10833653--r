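Package: dfcnstate
Title: Multiscale Dynamic Functional Network States via Graph-Convolutional
    Recurrent Attention Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sliding-window dynamic functional connectivity networks
    (dFCN) from ROI-averaged fMRI time series at multiple parcellation scales,
    classifies subjects with a graph-convolution + LSTM + temporal-attention
    (G-L-A) model trained under weighted cross-entropy and 5-fold
    cross-validation, fuses the single-scale models by majority voting,
    weighted voting or attention-feature fusion, and characterizes the
    attention-identified normal versus abnormal transient network states by
    edge-wise strength/variability tests, weighted modularity, global
    efficiency and state-transition dynamics.  Includes a seeded synthetic
    cohort generator with planted latent covariance states so the full
    pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    data.table,
    optparse,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    car
Config/testthat/edition: 3
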