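Package: immunoscore
Title: Immune-Infiltration Typing and a Prognostic Immune Score for
    Tumour Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies per-sample immune-cell infiltration from bulk
    expression by single-sample gene set enrichment (ssGSEA), clusters
    tumours by consensus non-negative matrix factorization with
    survival-informed rank selection, detects co-expression modules via
    a weighted network with topological overlap, screens hub genes by
    module membership and gene significance, and condenses hub-gene
    expression into a principal-component immune score dichotomized at
    the survival-optimal cutpoint.  Includes a synthetic-cohort
    generator with planted infiltration groups, co-expression modules
    and group-dependent progression-free survival, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
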