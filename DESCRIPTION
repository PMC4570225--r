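Package: smirna
Title: Small RNA Sequencing Analysis with Hairpin-Based miRNA Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA sequencing analysis pipeline for plant
    miRNA studies: five-class read filtering and collapsing of adapter-ligated
    tags, priority-based annotation against ncRNA/miRNA/repeat/gene references,
    known-miRNA quantification with isomiR profiling, novel miRNA discovery
    from genomic hairpin precursors with miRNA-star validation, exact-test
    differential expression between control and drought libraries,
    complementarity-based target prediction with degradome confirmation, and
    2^-ddCt qPCR analysis. A self-consistent synthetic-study generator with a
    ground-truth ledger provides an oracle for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
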