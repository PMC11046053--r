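Package: sitewalkr
Title: Transgene Integration-Site Discovery from Paired-End WGS by
    Informative-Read Classification, Junction Calling and Genome Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates and characterizes randomly integrated transgene
    constructs in engineered genomes from paired-end whole-genome
    sequencing. Classifies read pairs into informative categories
    (isolateral, flanking, chimeric, homologous), resolves fusion
    junctions at single-base resolution from soft-clipped alignments,
    extends the construct-anchored sequence by iterative
    assembly-and-remapping genome walking, and infers integer cassette
    copy numbers from normalized read depth. Includes a built-in
    seed-and-extend read mapper and Smith-Waterman local aligner with
    SAM interoperability, a synthetic-data module that generates
    integrant genomes with known truth together with paired-end reads,
    batch-culture time series and qPCR Ct tables, sliding-window
    enhancer-score aggregation, and bioprocess quantitation (integral
    viable cell density, specific productivity, delta-delta-Ct).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    zoo,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
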