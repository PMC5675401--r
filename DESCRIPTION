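Package: epilocus
Title: Locus-Scale Bisulfite Methylation, Small RNA Profiling, and qPCR
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for single-locus plant epigenomics built around
    a ~10 kb multicopy maize-style gene model. Provides clone-based bisulfite
    amplicon methylation calling by cytosine context (CG/CHG/CHH) with
    replicate-level genotype comparisons, size-class-resolved small RNA
    profiling with reads-per-million and 22-nt-anchored normalization,
    50-bp binned coverage and detection of regions that lose 24-nt siRNAs
    in an RdDM-deficient mutant, and Livak 2^-ddCt / percent-of-input
    qPCR and ChIP-qPCR quantification. Includes a fully seeded synthetic-data
    generator (locus with transposon fragments, bisulfite clone sets, small
    RNA libraries, Ct tables) with recorded ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
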