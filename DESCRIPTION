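Package: methylstab
Title: Methylation Stability and Motif Landscape Analysis for
    Restriction-Modification Target Sites
Version: 0.1.0
Authors@R:
    person("Methylstab", "Developers", email = "methylstab@example.org",
           role = c("aut", "cre"))
Description: Analysis of N6-methyladenine (m6A) modification at palindromic
    restriction-modification target motifs (GATC, CATG) in small genomes,
    built around single-molecule real-time (SMRT/PacBio) base-modification
    calls. Provides palindromic motif scanning with spacing and dispersion
    statistics, motif-free gap detection, sliding-window enrichment and
    gap depletion scoring with gene annotation, parsers for PacBio-style
    per-site modification GFF3/CSV outputs (ipdRatio, ModificationQV,
    coverage, methylated-read fraction), cross-replicate methylation
    stability classification, palindrome full/hemi/non-methylation state
    calling, and a seeded synthetic-methylome generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
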