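Package: charmod
Title: Differential Chromatin Accessibility Modules from ATAC-Seq Cut-Site
    Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of ATAC-seq experiments built around a
    merged peak universe: Tn5 cut-site quantitation with FRiP and TSS
    enrichment quality control, negative-binomial differential
    accessibility testing across all condition pairs with
    median-of-ratios normalization and moderated dispersions, k-means
    accessibility modules on the row-normalized condition-mean matrix,
    hypergeometric fold enrichment of modules against exhaustion-state
    region categories, and super-enhancer-associated gene calling from
    GREAT-style regulatory domains via elbow detection on the ranked
    gene/region-count curve. Includes a deterministic synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
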