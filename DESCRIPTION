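Package: iepbcc
Title: Bipartite Clustering Analysis of Interacting Enhancer-Promoter Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds sets of interacting enhancer-promoter pairs (IEPs) from
    chromatin-interaction data (Hi-C loop lists, sparse normalized contact
    matrices, and generic two-anchor link tables), applies cell-specific
    activity filters to enhancers and promoters, and characterizes how
    enhancers share their target genes through the bipartite clustering
    coefficient (BCC). Includes degree-preserving randomization with a
    binomial significance test, maximal-clique enhancer clustering with
    fully and partially shared target classification, cluster distance and
    consecutiveness statistics, super-enhancer and TAD overlap reports,
    and a synthetic-data generator with planted biclique structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
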