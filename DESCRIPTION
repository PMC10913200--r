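Package: triadex
Title: Parent-Hybrid Triad Expression Remodeling and Heterosis Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting transcriptome remodeling in F1 hybrids
    relative to their parents. Implements pairwise differential-expression
    calling on parent-parent-hybrid triads, the fourteen-subcategory /
    five-major-category expression remodeling classification (additive,
    parent-biased dominant, transgressive, conserved), decomposition of
    hybrid differentially expressed genes into inheritance sets (PEGs, HEGs,
    copDEGs, DIGs, H&P) with maternal-origin attribution, mid-parent and
    better-parent heterosis indices, hypergeometric GO-term enrichment with
    Benjamini-Hochberg correction, hub-gene screening over focal processes,
    and concordance analysis between seed DNA-methylation remodeling (CCGG /
    CCWGG restriction-site contexts) and seedling expression remodeling.
    Includes a negative-binomial simulator that plants remodeling classes,
    differentially methylated sites and phenotype heterosis as ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    MASS,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
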