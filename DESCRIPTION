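Package: DrugNetEvo
Title: Evolution and Robustness Analysis of Drug Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how drug-drug interaction (DDI) and bipartite
    drug-target interaction (DTI) networks evolve across versioned releases of
    a drug database. The package parses DrugBank-dialect XML releases, applies
    an approved-human-drug filter, builds monopartite DDI and bipartite DTI
    networks, and computes the standard complex-network summary statistics and
    node centralities (degree, betweenness, closeness, eccentricity,
    eigenvector, PageRank). Degree and centrality distributions are fitted
    with discrete or continuous power-law maximum likelihood using
    Clauset-Shalizi-Newman lower-cutoff selection, first-digit distributions
    are tested against Benford's law with chi-squared, Wasserstein and
    sum-of-squared-deviation distances, and an edge-injection simulation
    quantifies the robustness of centrality-based node rankings (Kendall tau)
    and of the power-law exponent when a fraction of the unknown interaction
    universe is assumed present. A seeded synthetic-data generator emulates
    versioned DDI/DTI releases so the whole pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    utils,
    tools,
    igraph,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Pharmacogenomics, Software
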