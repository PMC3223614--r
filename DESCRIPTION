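Package: gosieve
Title: De-Replication of Redundant Gene Ontology Enrichment Categories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes gene-set enrichment results in which many
    significant Gene Ontology (GO) categories are redundant because identical
    or nearly identical sets of genes map to them. Pairwise similarity between
    categories is measured by a one-tail Fisher's exact p-value on gene-set
    overlap; a p-value threshold chosen via a nominal number of merged pairs
    defines a category graph, which is decomposed into maximal cliques by a
    complete-linkage fixed-point algorithm in which a category may belong to
    several groups. Merged groups are collapsed into a reduced clustered image
    map (CIM) and a binary META CIM showing the grouping pattern, with
    average-linkage Euclidean ordering and heatmap rendering. Includes a
    synthetic-data generator with planted redundant groups for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
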