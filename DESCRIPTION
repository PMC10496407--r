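Package: sdweaver
Title: Targeted Iterative Assembly of Segmental Duplications from Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Anchor-based targeted assembler for segmental-duplication-rich
    genomic regions sequenced with error-prone long reads. Starting from a
    unique anchor sequence, each iteration recruits reads with a minimizer
    index, separates reads by copy of origin using paralogous sequence
    variants (cis-morphisms) called from a homopolymer-compressed pileup,
    assembles the selected cluster into a consensus contig and extends the
    anchor. Includes a simulator of collapsed segmental duplications evolving
    on tree topologies with configurable read error models, and an evaluation
    layer that assigns contigs to truth units and scores assemblies with
    Phred-scaled alignment identity.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    igraph,
    Biostrings,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
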