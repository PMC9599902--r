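Package: a2gcn
Title: Attention Graph Convolutional Networks with Unsupervised Domain
    Adaptation for Brain Connectome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-site classification of brain functional-connectivity
    networks with an attention-augmented graph convolutional network trained
    under discrepancy-based unsupervised domain adaptation (mean-absolute-error
    alignment of node embeddings plus CORAL covariance alignment of graph
    representations).  Builds Pearson-correlation connectivity graphs from ROI
    time series, fits the model with a two-stage Adam schedule, and provides
    centrality/SVM, deep-network and adversarial baselines, a synthetic
    two-site connectome cohort generator, seven classification metrics, a
    covariance-Frobenius site-shift statistic, and attention-based ROI
    ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
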