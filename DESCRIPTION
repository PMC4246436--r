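Package: blockcor
Title: Balanced Block Scheduling for Large Pairwise Correlation Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes large symmetric subject-by-subject correlation and
    distance matrices (Euclidean, Pearson, Spearman, Kendall tau-b) from
    gene-expression matrices by splitting subjects into contiguous blocks,
    scheduling the unordered block pairs across workers with a balanced
    circular assignment so that every worker carries either the ceiling or
    the floor of the average load, and assembling the per-pair coefficient
    tiles into the full symmetric matrix.  Includes a map-side "combiner"
    execution mode that decouples the worker count from the block count, a
    merge-sort Kendall tau-b kernel, hierarchical clustering of subjects
    for stratification, a seeded synthetic expression-matrix generator
    with planted cluster structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    parallel,
    readr,
    stats,
    utils,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
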