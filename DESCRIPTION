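Package: herbnetdiff
Title: Multiscale Network Diffusion for Herbal Candidate Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Prioritizes medicinal herbs and their active compounds against a
    disease by network diffusion on a multiscale interactome. Builds a typed
    graph joining a protein-protein interaction layer to a hierarchy of
    biological functions, attaches herb, compound and disease entities to
    their protein sets, computes diffusion profiles by biased random walk
    with restart, and scores entities by the Pearson correlation of their
    profiles with the disease profile together with hypergeometric overlap
    and fold enrichment. Includes a synthetic-data generator with a planted
    positive-control herb, gene-set over-representation analysis against GMT
    libraries, top-k mechanism subnetwork extraction with GraphML/SIF
    export, and a one-command pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
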