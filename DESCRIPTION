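Package: netdiv
Title: Network Diversity Score and Structural Complexity Measures for Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-based structural complexity scoring for undirected
    networks. Implements the network diversity score (NDS), a multiplicative
    combination of module density, motif growth rate, module-size variability
    and Laplacian-eigenvalue variability, estimated over a sample of networks
    drawn from a population, together with sixteen classical graph complexity
    descriptors (information-theoretic, distance-based, degree-based and
    spectral), seeded generators for ordered, random and complex network
    populations, random-walk subnetwork sampling, and an evaluation harness
    for parameter sweeps and three-class separation scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
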