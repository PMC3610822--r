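Package: mycodiff
Title: Two-Color Microarray Pipeline for Streptomyces Developmental
    Transcriptomes with a Genomic-DNA Common Reference
Version: 0.1.0
Authors@R:
    person("Array", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantification and gene-selection pipeline for two-color
    expression microarrays hybridized against a genomic-DNA common
    reference, as used to compare the vegetative (MI) and multinucleated
    (MII) mycelial stages of Streptomyces coelicolor. Implements
    background correction with a surrogate-intensity rule, log2
    cDNA/gDNA abundance values (Mg), probe validity weighting, weighted
    cyclic-loess and median normalization, gene-level linear models with
    empirical-Bayes moderated t-statistics and Benjamini-Hochberg FDR
    control, a conservative multi-contrast reliability filter, the
    fold-change/conservation candidate cascade, and delta-delta-Ct
    relative quantification for qPCR cross-validation. Ships a
    synthetic-data generator that emulates the 4-stage x 3-replicate
    study design with known per-gene effects, plus published per-gene
    abundance tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
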