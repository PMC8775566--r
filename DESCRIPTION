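Package: sensigwas
Title: Genotype- and Age-Specific Drug-Response Mapping in Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping genotype- and age-specific
    responses to a drug treatment in panels of inbred lines (such as the
    Drosophila Genetic Reference Panel). Computes mass-adjusted least-squares
    line means, the Falconer sensitivity index quantifying each genotype's
    treatment response, single-marker genome-wide association scans on line
    means (with an optional trait-value cofactor for sensitivity scans),
    among-line variance components and genetic correlations across ages and
    treatments, candidate-variant-to-gene window annotation, and a
    bridged-subnetwork permutation test over a gene-interaction graph. A
    synthetic-data module generates inbred-panel genotypes, phenotypes, gene
    models, and interaction networks with known ground truth so that every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    car,
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
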