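Package: teloci
Title: Locus-Level Analysis of Transposable-Element Transcription
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transposable-element (TE) expression candidates at the
    level of individual genomic loci from short-read RNA-seq alignments using
    three complementary read-evidence filters (unique-mapping counts,
    multi-mapping-inclusive coverage, and discordant "dangler" read pairs),
    classifies candidates by trackability, length integrity, and hierarchical
    genomic location with chi-square location-bias tests, dates LTR
    retrotransposon insertions from LTR-pair divergence (Kimura two-parameter),
    calls differentially expressed TE loci and genes on time-course count
    matrices and measures expression-pattern concordance between co-localised
    TE-gene pairs, classifies long-read cDNA evidence at TE loci (transcription
    start, origin relative to genes, breadth of coverage, alignment-end types,
    full-length transcript evidence), and types alternative-splicing features
    and isoform productivity including premature-termination-codon localisation
    relative to TE-overlapping retained introns. A synthetic-data module
    generates fully specified toy genomes, annotations, alignments, and count
    matrices with a ground-truth manifest so that every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    cluster,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    ape,
    DESeq2,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
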