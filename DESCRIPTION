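Package: pollenlnc
Title: Heat-Responsive lncRNA Discovery and Regulatory Network Inference in
    Wheat Pollen Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico workflow for identifying long non-coding RNAs
    (lncRNAs) that respond to heat stress during pollen development in
    hexaploid wheat, and for inferring their regulatory roles. Implements a
    candidate-filter cascade (gffcompare class codes, length, a three-scorer
    coding-potential consensus, protein-domain veto), TMM/CPM normalisation
    with a nonparametric noise-distribution differential-expression test,
    cis/trans target inference from co-expression with an RNA-RNA
    hybridisation free-energy filter, plant-rule miRNA target scoring with
    sponge/precursor classification, Fisher GO enrichment with ancestor
    rollup, and sequence-homology conservation analysis with neighbour-joining
    trees. A synthetic-data generator emulates the full study design with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
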