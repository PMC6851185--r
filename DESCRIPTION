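Package: splicemosaic
Title: Combinatorics of Mutually Exclusive Alternative Splicing in
    Hypervariable Receptor Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling genes whose diversity arises from
    mutually exclusive exon clusters, optional exons and alternative
    terminators, as found in arthropod Dscam immune receptors. Provides a
    validated gene-model container with GFF3/FASTA serialization, exact
    isoform counting and enumeration under splice constraints, mature
    transcript assembly with junction-aware translation and consensus
    motif scanning, inference of exon types from transcript evidence,
    detection of tandem arrays of near-duplicate exons in genomic DNA,
    amplicon clone assignment with per-tissue detection matrices,
    alignment conservation profiles with epitope-window extraction, and a
    seeded synthetic-data generator. Ships a worked model of the Penaeus
    monodon Dscam gene (shrimp; 44 exon slots, over 21 million isoforms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
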