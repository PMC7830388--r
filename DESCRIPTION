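Package: regulonkit
Title: Regulon Inference from ChIP-Seq Occupancy and RNA-Seq Differential
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the direct target gene set (regulon) of a
    prokaryotic transcription factor by integrating ChIP-seq and RNA-seq
    data, modelled on the analysis of the archaeal copper-responsive
    regulator CopR in Pyrococcus furiosus.  Implements peak-caller-free
    ChIP-seq occupancy quantification (fragment extension, depth scaling,
    IP/input ratio tracks, windowed per-gene occupancy), a simplified
    negative-binomial differential-expression test with median-of-ratios
    normalisation and Benjamini-Hochberg correction, a two-criterion
    ChIP/RNA integration rule defining the regulon, ZOOPS-EM motif
    discovery with exact p-value PWM scanning and FDR control,
    TSS-anchored nucleotide-enrichment and trinucleotide DNA-bendability
    profiling, and a seeded synthetic-data generator that plants a known
    regulon and binding motif for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
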