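Package: aluscan
Title: Population-Scale Detection and Genotyping of Polymorphic Alu Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and genotypes polymorphic Alu elements from paired-end
    sequencing alignments across many individuals at once. Genotypes Alu
    deletions at annotated reference Alu loci from read-pair classes (internal,
    split, across) with an explicit genotype likelihood model built on the
    per-library insert-length distribution; discovers Alu insertions absent
    from the reference by clustering discordant read pairs pooled across
    individuals, refines breakpoints with a two-level split-read voting
    scheme against a panel of Alu consensus sequences, and genotypes carriers
    by in-silico insertion. Includes a truth-aware paired-end read simulator
    for benchmarking and confusion-matrix evaluation utilities (sensitivity,
    false discovery rate, Mendelian consistency).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    optparse,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
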