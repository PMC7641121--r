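Package: coexmr
Title: Mutual-Rank Gene Co-Expression Networks with Tissue and
    Enrichment Overlays
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Builds signed gene co-expression networks from FPKM
    expression matrices using all-pairs Pearson correlation and
    mutual-rank (MR) edge scoring.  Provides replicate summarisation and
    expression calling for multi-tissue RNA-seq designs, MR-bounded
    neighbourhood queries, tissue-expression and differential-expression
    overlays, and overlap-based gene-set enrichment by Fisher's exact
    test with Benjamini-Hochberg FDR control.  Includes a seeded
    synthetic-data generator that plants co-expressed modules,
    tissue-specific and silent genes, matched gene sets and DEG tables,
    so the whole pipeline can be exercised end to end without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
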