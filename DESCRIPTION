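Package: ccsRegulome
Title: Regulatory Genomics of Fusion Transcription Factor Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the regulatory genome bound by a fusion
    transcription factor, built around ChIP-seq binding sites in clear cell
    sarcoma models. Provides genomic-interval I/O and overlap arithmetic,
    binding-site annotation relative to gene models (promoter, intragenic,
    intergenic), a gap-tolerant TGA/TCA trinucleotide repeat-tract scanner,
    fixed-motif classification of binding-site sequences (ATF/CREB canonical
    and variant motifs, AP1), ROSE-style super-enhancer calling from H3K27ac
    signal (12.5 kb stitching, input-normalised signal, tangent cutoff),
    chain-based coordinate liftover with reciprocal cross-species
    super-enhancer synteny matching, integration of binding sites and
    chromatin loops with differential-expression results, and seeded
    synthetic-data generators with machine-readable ground truth for testing
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
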