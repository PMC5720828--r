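Package: spliceflow
Title: Genome-Guided Transcript Assembly and Quantification from Spliced
    Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles transcripts from coordinate-sorted spliced RNA-Seq
    alignments and quantifies their abundances without requiring a gene
    annotation. Reads are parsed into per-locus splicing graphs whose nodes
    are subexons; assembly is solved as a constrained minimum path cover by
    a min-weight min-flow circulation with paired-end subpath constraints;
    quantification collapses read-pairs into subexon-path counts and fits a
    latent class model by an EM algorithm, reporting FPKM and TPM. Includes
    a read-pair simulator for multi-isoform toy genes, evaluation metrics
    (proportionality correlation, MARD, intron-chain matching), and a
    quantification-only mode driven by an existing GFF3 annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
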