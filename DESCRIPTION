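Package: gdinet
Title: Gene-Gene Dynamics Influence Networks from Boolean Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the dynamical influence of one gene on another in a
    signed gene-gene molecular interaction network using a synchronous
    Boolean network model with randomized nested canalyzing update rules.
    A time-limited in-silico knockout of a source gene perturbs the state
    trajectory; the attractor-level state sequence of every target gene is
    compared between wild-type and mutant runs with an exact-rational
    alignment distance, averaged over sampled initial states, and the
    resulting influence matrix is thresholded into a dynamics-influence
    network. Includes structural analyses (shortest paths, path and
    feedback-loop counts, degree statistics and correlations), preferential
    attachment and degree-preserving random-network baselines, and a
    knockout-expression validation pipeline with a synthetic data
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
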