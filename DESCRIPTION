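Package: wrkyfam
Title: WRKY Transcription-Factor Family Identification, Classification and
    Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide characterization of the WRKY
    transcription-factor family, built around the sandalwood (Santalum album)
    SaWRKY family. Detects WRKY heptapeptide domains and zinc-finger patterns
    by a motif grammar, types the zinc finger (C-C-H-H, C-C-H-C and variants),
    classifies members into groups I/II/III and subgroups IIa-IIe by rules
    plus neighbor-joining phylogeny with bootstrap support, extracts 2-kb
    promoters and scans W-box (C/T)TGAC(C/T) cis-elements to predict target
    genes with hypergeometric pathway enrichment, computes RPKM/log2 tissue
    expression matrices, and calls hormone (SA/MeJA) regulation from RT-qPCR
    Cq tables by the 2^-ddCq method. Ships seeded synthetic-data generators
    that plant known domains, W-box counts and expression effects so every
    stage is verifiable without the S. album genome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
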