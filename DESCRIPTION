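Package: cypome
Title: Cytochrome P450 Identification, Classification and Pan-CYPome
    Analysis Across Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for cytochrome P450 (CYP) analysis of
    multi-genome protein FASTA collections. Pools proteomes, reduces
    redundancy by greedy centroid clustering at a configurable identity
    threshold (default 55%), identifies CYPs by scanning cluster centroids
    against position-specific scoring matrices of the conserved P450 domain
    with empirically calibrated E-values, assigns family and subfamily
    names by best-identity search against a named reference set using the
    standard 40%/55% nomenclature rules, and builds a Genome-CYP Matrix
    (GCM). Downstream GCM analyses include pan- and core-CYPome rarefaction
    with power-law regression, CYP co-occurrence networks, hierarchical
    genome clustering with heatmaps, and CYP frequency clouds. A
    deterministic synthetic-data generator provides reference sets,
    proteomes and ground-truth manifests for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    graphics,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
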