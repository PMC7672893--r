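Package: mcmcModules
Title: Soft Classification of Active Modules in Interaction Networks by MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies active modules in biological interaction networks as a
    soft classification problem. Vertex p-values are modelled with a
    beta-uniform mixture, connected subgraphs are sampled from the posterior
    over modules with a Metropolis-Hastings chain (fixed or variable module
    order), and the samples yield per-vertex membership probabilities, false
    discovery rates of vertex sets, expected AUC ROC of rankings, and a
    connectivity-preserving vertex ranking from which nested modules can be
    extracted at any FDR level. Includes exact small-instance oracles and a
    synthetic-instance generator for benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
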