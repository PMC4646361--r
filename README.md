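# netcentral

Comprehensive vertex-centrality analysis and essential-node prioritization
for biological (and other) networks.

## What problem this solves

In network biology the *centrality–lethality rule* observes that
structurally central proteins in protein–protein interaction (PPI)
networks are enriched for essential genes, so centrality indices are used
to prioritise candidate essential genes, biomarkers and drug targets.  No
single index captures every notion of "central", and most network tools
expose only a dozen classics.  `netcentral` implements a registry of **53
centrality measures** across five families, plus the downstream
essentiality workflow: ranking vertices per measure, scoring essential-node
enrichment in the top *k*, and aggregating many per-measure rankings into
one consensus ordering.

The five families, with representative definitions in standard notation
(`d(v,u)` geodesic distance, `σ_st` the number of shortest *s*–*t* paths,
`A` the adjacency matrix, `L` the graph Laplacian):

| family | measures | flavour |
|---|---|---|
| distance | Freeman/Latora/Dangalchev closeness, barycenter, Lin, eccentricity, radiality, centroid value, decay, average distance, closeness vitality, geodesic K-path | functions of `d(v,u)` |
| neighborhood | degree, strength, lobby, leverage, local clustering, topological coefficient, k-core, semi-local, ClusterRank, diffusion degree, MNC, DMNC, cross-clique, Burt's constraint, graphlet degree | local structure around `v` |
| feedback | eigenvector, Katz, alpha, Bonacich power, Hubbell, PageRank, LeaderRank, HITS, SALSA, subgraph, Laplacian, entropy, community | fixed points / spectra of `A` |
| flow | betweenness `Σ σ_st(v)/σ_st` (Brandes), stress, load, max-flow betweenness, current-flow betweenness/closeness, information, communicability betweenness, Markov | traffic carried by `v` |
| perturbation | bottleneck, bridging, EPC (edge-percolated component), pairwise disconnectivity | damage done by removing `v` |

Networks can be directed or undirected, weighted or unweighted, and are
read from five formats: whitespace edge list (`.txt`), Pajek (`.net`),
UCINET DL (`.dl`), GML (`.gml`) and GraphML (`.graphml`).  Results export
as a per-vertex CSV score table and as a score-annotated GML file.

The consensus step minimises the total Spearman footrule distance
`Σ_lists Σ_i |rank_consensus(i) − rank_list(i)|` over permutations, by
exhaustive search on small universes and by a seeded genetic algorithm
(order crossover, swap mutation, elitist selection) otherwise.

## Worked example

The packaged demo network is Zachary's karate club (34 vertices, 78
edges).

```r
library(netcentral)

g  <- make_fixture("karate")
sv <- centrality_score(g, "betweenness")
sv
#> <score_vector> betweenness over 34 vertices
#>        v1       v34       v33        v3       v32
#> 231.07143 160.55159  76.69048  75.85079  73.00952

rank_vertices(sv, top_m = 5)
#> <ranked_list> betweenness top of 34 vertices: v1 > v34 > v33 > v3 > v32

lists <- lapply(c("degree", "closeness_latora", "pagerank", "betweenness"),
                function(id) rank_vertices(centrality_score(g, id)))
aggregate_ranks(lists, seed = 42)
#> <rank_aggregation> genetic / spearman objective 270
#>   consensus: v34 > v1 > v33 > v3 > v2 > v32 > v4 > v14 > v9 > v24 ...
```

The two club leaders (`v1`, Mr Hi, and `v34`, the officer) dominate every
ranking: `v1` carries a betweenness of 231.07 — about 44% of the
(33·32)/2 = 528 possible source–target pairs route through it — and the consensus over four
measures puts the two leaders first with a footrule objective of 270.

With an essential-node list (one label per line), the enrichment readout
is:

```r
ess <- read_essential_set("essentials.txt")
topk_enrichment(rank_vertices(centrality_score(g, "closeness_latora")),
                ess, k = 10)
```

Batch jobs mirror a submission workflow — every measure, one manifest,
reproducible from one seed:

```r
cfg <- job_config("fixture:karate", list_measures()$id,
                  output_dir = "work", seed = 1)
rec <- run_job(cfg)       # writes scores.csv, scores.gml, manifest.json
```

or from the shell via `inst/cli/netcentral`
(`run`, `measures`, `enrich`, `aggregate` subcommands).

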