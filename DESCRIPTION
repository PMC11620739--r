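Package: flexattractor
Title: Self-Organizing Grid-Cell Networks and Topological Analysis of
    Their Population Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a self-organizing network of grid cells driven by
    place-cell-like spatial inputs with Hebbian feedforward plasticity,
    neural adaptation, global inhibition, and fixed recurrent collaterals
    of configurable architecture (two-dimensional torus, one-dimensional
    ring or stripe, fragmented, or none).  Quantifies the resulting maps
    (autocorrelograms, gridness, spacing, population alignment) and
    analyses the topology of the population activity with tools from
    topological data analysis: k-nearest-neighbour geodesic distances,
    Vietoris-Rips persistent homology over prime fields, automated Betti
    number estimation, local PCA dimension, local homology for boundary
    and singularity detection, orientability testing, and closed-surface
    classification.  Includes synthetic fixtures (ideal grid populations
    and samples of known manifolds) so the full analysis stack can be
    exercised without long training runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
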