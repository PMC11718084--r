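Package: mcesdist
Title: Myopic Maximum Common Edge Subgraph Distances for Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Structural distances between small-molecule graphs based on the
    weighted Maximum Common Edge Subgraph (MCES). Provides provably correct
    lower bounds (weighted-degree and per-element bipartite-matching bounds)
    for fast rejection of dissimilar pairs, exact computation of the weighted
    MCES distance via an integer-program formulation solved by an internal
    branch-and-bound (optionally by an external MILP backend), and the
    double-thresholded "myopic" distance that is a metric. Includes batch
    pairwise-distance tables, nearest-neighbor and dataset-coverage
    statistics, a synthetic molecular-graph generator, and a brute-force
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    clue,
    igraph,
    jsonlite,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Optional Python (>= 3.8) with rdkit for SMILES parsing
    and scipy for the external MILP backend.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
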