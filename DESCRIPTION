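Package: panmap
Title: Long-Read Mapping to Pangenome Variation Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Seed-chain-extend mapping of long sequencing reads to pangenome
    variation graphs read from GFA. Implements snarl/chain decomposition of
    bidirected sequence graphs, a hierarchical minimum-distance index, zip
    codes and zip code trees for fast seed-to-seed graph distances, weighted
    minimizer seeding over embedded haplotype walks, two-pass co-linear
    chaining with a Minimap2-style gap cost, and hybrid base-level extension
    (wavefront alignment against local haplotypes with banded graph alignment
    and X-drop tail alignment as fallbacks). Writes alignments as GAF.
    Includes a synthetic pangenome and read simulator and a mapping
    evaluation module for MAPQ calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    data.table,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
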