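Package: ragony
Title: Ranking Hierarchies in Directed Graphs by Agony Minimisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection of ranking hierarchies (ordered partitions of nodes)
    in directed graphs by minimising generalised agony, a cost charged to
    links that point against the hierarchy. Includes an exact
    minimum-cost-circulation solver for the linear penalty, exhaustive
    enumeration over ordered partitions for small graphs, and a greedy
    feedback-arc-set heuristic; a Ranked Stochastic Block Model sampler
    with planted rankings; first-order expected-hierarchy estimates with
    closed-form resolution thresholds for merged, split and inverted
    candidate rankings; partition-comparison metrics; iterated agony
    refinement; and a seeded sweep runner for phase-diagram experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
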