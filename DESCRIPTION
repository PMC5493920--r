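Package: dynblock
Title: Dynamic Stochastic Block Models for Snapshot Sequences of
    Ecological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based clustering of dynamic networks observed as a
    sequence of snapshots, such as animal contact networks recorded over
    days or seasonal food webs. Each node follows a hidden Markov chain
    over latent groups and dyad values are emitted from zero-inflated
    multinomial (or Bernoulli) distributions whose parameters depend on
    the endpoint groups and the time step. Provides a generative
    simulator, variational expectation-maximisation inference with exact
    per-node forward-backward smoothing, integrated classification
    likelihood (ICL) and elbow model selection, and post-fit summaries:
    group-pair connectivity and intensity tables, alluvial membership
    flows, stability statistics and contingency tables against external
    labels. Supports directed and undirected networks, self-loops, edge
    weights binned into ordinal categories, and nodes entering or leaving
    the network over time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ggplot2,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
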