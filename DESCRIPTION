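Package: proteoHarm
Title: Harmonization of Multi-Study Protein and Gene Identifier Lists
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Harmonizes protein and gene identifier lists from heterogeneous
    proteomics studies so they can be compared in a meta-analysis. Provides
    filtering of protein groups (wrong organism, unreviewed, obsolete,
    contaminant and decoy entries), re-mapping of protein accessions to gene
    names (including FASTA-header derived names), reduction of synonym-laden
    gene cells to a canonical namespace, and cross-organism ortholog mapping
    through Ensembl gene identifiers, each with full row-level and
    identifier-level loss/gain logging. Downstream, it offers multi-study
    intersection analysis and network-based mechanism mining: Multi-Steiner
    tree connector search over a protein-protein interaction network,
    TrustRank and centrality scoring, and ranking of drugs targeting the
    mined mechanism. All annotation knowledge is supplied through a pluggable
    local-snapshot provider, and a deterministic synthetic-fixture generator
    makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
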