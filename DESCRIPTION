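Package: riboscape
Title: Integrated Ribo-Seq and RNA-Seq Analysis of Translational Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for joint analysis of ribosome-profiling (Ribo-seq) and
    RNA-seq data at the transcript level: footprint length filtering and
    quality control, P-site offset estimation and trinucleotide periodicity,
    FPKM normalization and translation-efficiency (TE) quantification,
    negative-binomial Wald tests for differential transcription, translation
    and translation efficiency with Benjamini-Hochberg correction, a
    five-category divergence classifier (Transcription, Translation/TE,
    Homodirection, Opposite, Unchanged), CDS sequence-feature analysis
    (length, GC, normalized minimum free energy) across TE bins, and upstream
    open reading frame (uORF) detection with four-score translatability
    classification (ORFscore, ribosome release score, Fickett TESTCODE,
    hexamer log-likelihood). Includes a seeded synthetic-data generator that
    emulates a two-group, three-replicate testis Ribo-seq/RNA-seq study with
    planted ground truth for every downstream stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    MASS,
    Rcpp,
    S4Vectors,
    data.table,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
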