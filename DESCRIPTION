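Package: netcentral
Title: Comprehensive Vertex Centrality Analysis and Essential-Node
    Prioritization for Biological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a large registry of vertex centrality indices
    (distance, neighborhood, feedback, flow and perturbation families) on
    directed or undirected, weighted or unweighted networks. Reads and
    writes edge-list, Pajek, UCINET DL, GML and GraphML network files,
    exports per-measure score tables as CSV and score-annotated GML, and
    implements an essentiality workflow for protein-protein interaction
    networks: top-k enrichment of essential nodes per measure and genetic
    algorithm rank aggregation of per-measure orderings into a consensus
    ranking under the Spearman footrule distance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
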