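Package: epibuffr
Title: Epigenetic Buffering of Subgenome Diversity in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting how a chromatin factor buffers the
    expression of subgenome-diversified genes in an allopolyploid genome.
    Implements homoeolog copy-number cataloguing from orthogroup tables,
    L1-penalized logistic regression for ranking trans-factors that
    preferentially bind unbalanced homoeolog groups, phylostratigraphic
    gene-age assignment, sliding-window nucleotide diversity and
    captured-divergence quadrant analysis, spike-in (RRPM) and M-value
    differential ChIP signal calling with direct-target labeling,
    hypergeometric gene-set enrichment and contrast matching, plus a
    seeded synthetic allopolyploid world generator with a ground-truth
    manifest for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
LinkingTo: Rcpp
Suggests:
    glmnet,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
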