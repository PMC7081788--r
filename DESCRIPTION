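Package: multiplexrank
Title: Consensus Ranking of Node Centrality in Multiplex Social Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes multiplex (multilayer) network centrality by consensus
    ranking: a per-layer centrality metric (weighted eigenvector, degree, or
    betweenness) is chosen to suit each layer's structure, layer centralities
    are collapsed into rank tiers by one-dimensional complete-linkage
    hierarchical clustering with an explained-variance cut, and tier ranks are
    aggregated across layers by Borda count. Includes pairwise Spearman
    comparison of layer rankings, negative-binomial regression of reversed
    consensus ranks on node attributes with AICc model selection and
    node-label permutation inference, and a synthetic generator of multiplex
    primate-style social groups (latent dominance hierarchy, matrilineal kin
    bias, five behavioural layers) for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    MASS,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
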