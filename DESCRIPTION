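Package: peanut
Title: Network-Propagation Pathway Enrichment Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pathway enrichment analysis that diffuses absolute gene
    expression scores over a protein-protein interaction network by random
    walk with restart and scores pathways with a three-stage statistical
    cascade (Kolmogorov-Smirnov, Mann-Whitney U, permutation test), each
    stage followed by Benjamini-Hochberg correction. Also provides the
    standard comparator transforms (signed preranked GSEA, absolute-value
    GSEA, and neighbor-averaging NGSEA) over a shared preranked enrichment
    core, readers and writers for .rnk, GMT and edge-list formats, a
    deterministic synthetic-data generator with a planted connected signal
    module, and utilities for benchmarking methods by the rank of a known
    target pathway.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
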