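Package: mrnaqc
Title: Quality Control Analytics for mRNA Vaccine Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures critical quality attributes of in vitro transcribed
    mRNA vaccines and their plasmid templates from aligned long- or
    short-read sequencing: per-nucleotide error profiles with baseline
    subtraction, pileup-majority consensus and variant listing, full-length
    versus truncated transcript integrity classification, poly(A) tail
    length estimation with homopolymer deletion-rate correction, cryptic
    transcription start site detection, antisense and contaminant read
    triage, and N1-methylpseudouridine miscall-signature scanning. Includes
    a deterministic synthetic read simulator that emits FASTQ plus
    edit-exact truth alignments so every analytic can be validated against
    known ground truth, and plasmid/mRNA report drivers that emit
    machine-readable QC reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
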