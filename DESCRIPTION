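Package: corrnet
Title: Correlation-Based Network Construction, Topology, and Differential Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds correlation-based networks from samples-by-variables data
    matrices such as metabolite abundance tables. Computes pairwise
    correlation coefficients (Pearson, Spearman, Kendall) on
    pairwise-complete observations together with raw and multiplicity
    adjusted p-values, selects significant edges by magnitude and
    significance thresholds, assembles undirected weighted networks, and
    reports the usual graph-topology metrics (density, diameter, global
    transitivity, betweenness centrality, clustering coefficients, degree
    distribution power-law fit). Condition-specific networks can be compared
    through union, intersection, and difference operations with hub ranking
    by betweenness centrality. Includes readers and writers for the
    exchange formats used around Cytoscape (dual-triangle p-value tables,
    three-column tab-delimited edge tables, SIF, GraphML), a synthetic
    two-condition data generator with planted correlation blocks for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
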