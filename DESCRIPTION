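Package: bovicnv
Title: Copy Number Variation and Common Deletion Polymorphism Discovery
    from SNP Array Intensity Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering copy number variants (CNVs) and common
    deletion polymorphisms in livestock cohorts genotyped on Illumina-style
    SNP BeadChips. Reads Final-Report-like intensity/genotype exports (log R
    ratio, B allele frequency, total intensity R), applies sample-level
    quality control, calls per-sample CNV segments with a hidden Markov model
    over LRR/BAF, aggregates calls into population CNV regions with frequency
    and gain/loss classification, screens sire-steer pedigrees for
    deletion-induced Mendelian inconsistencies, scans pairwise intensity
    ratios for hidden deletions, and quantifies copy number from TaqMan qPCR
    replicates by the comparative CT method. A seed-reproducible synthetic
    cohort generator with embedded CNV truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
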