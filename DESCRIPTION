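Package: exprss
Title: Tag-Seq Expression Profiling from Randomly Sheared cDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of EXPRSS-style 3' tag sequencing libraries:
    variable-length barcode demultiplexing, FASTX-style quality and artifact
    filtering, a tag-to-gene assignment cascade over two-pass (genome then
    transcript) alignments with fractional multi-mapper weights, strand-aware
    sense/antisense count matrices, distance-from-3'-end profiles, alternative
    polyadenylation and antisense peak calling, novel-transcription region
    detection, poly(A) site assignment from paired-end reads, tags-per-million
    normalization with detection filtering and replicate QC, and a synthetic
    sheared-cDNA library simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    optparse,
    graphics,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
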