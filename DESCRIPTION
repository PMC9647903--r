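Package: zfplinker
Title: Cluster-Level Analysis of KRAB Zinc-Finger Protein Genes and
    Linker-Targeted Multi-Copy sgRNA Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cluster-level analysis of KRAB zinc-finger protein
    (KRAB-ZFP) gene families. Calls gene clusters from genomic coordinates
    under a neighbour-gap rule, decomposes C2H2 zinc-finger arrays into
    overlapping ZnF and linker tiles and extracts DNA-binding fingerprint
    triplets, builds gene-by-fingerprint occurrence matrices with
    cluster-exclusivity statistics, computes positional frequency and
    information-content (sequence-logo) profiles with conserved NGG PAM
    discovery, enumerates and ranks multi-target sgRNA candidates from
    cluster-specific linker sequences with exact-match cut-site prediction
    and cluster-specificity scoring, and selects highly expressed clusters
    from TPM tables. A synthetic KRAB-ZFP family generator with planted
    ground truth makes every pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    GenomicRanges,
    IRanges,
    rtracklayer,
    optparse
Config/testthat/edition: 3
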