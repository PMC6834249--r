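Package: pollinet
Title: Pollen Metabarcoding Foraging Networks for Bumblebee Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pollen DNA-metabarcoding surveys of
    bumblebee colonies. Filters false-positive OTUs from per-sample read
    counts with a per-sample ROC/Youden threshold on a two-group
    overdispersed-Poisson fit, builds individual-by-plant bipartite foraging
    networks, computes node-level (degree, resource range, proportional
    generality, paired difference index, d', closeness centrality) and
    network-level (link density, connectance, NODF/WNODF, Barber modularity,
    H2', generality, vulnerability) indices, compares paired networks with a
    permutation swap test, runs PERMANOVA on pollen composition, and
    estimates Chao2 sampling coverage. Includes a seeded synthetic-data
    generator emulating the colony-by-phase sampling design so the whole
    pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
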