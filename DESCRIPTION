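Package: evogeo
Title: Evolutionary Distance Embedding for Protein Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: De novo protein-protein interaction prediction by embedding an
    evolved training sub-network into a low-dimensional geometric space.
    A minimum spanning tree of the interaction network's largest connected
    component is evolved under duplication/neofunctionalization, preferential
    attachment, or random mutation models; the resulting distance matrix is
    embedded by classical multidimensional scaling (Isomap) or non-centered
    SVD; candidate pairs are scored with a Bayesian confidence derived from
    Gaussian mixture densities of embedded distances, and predictions are
    evaluated with ROC and precision-recall cross-validation over repeated
    spanning-tree draws. Includes seeded generators for geometric-random and
    duplication-divergence networks used as test fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
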