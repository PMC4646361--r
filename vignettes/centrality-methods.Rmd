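---
title: "Centrality measures, conventions and the essentiality workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality measures, conventions and the essentiality workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcentral)
```

`netcentral` computes a registry of 53 vertex-centrality indices on
directed/undirected, weighted/unweighted networks and implements the
essential-node prioritization workflow built on top of them.  Many of
these indices have several inequivalent formulations in the literature;
this vignette records exactly which formulation the package computes,
the conventions adopted where the literature is silent or ambiguous, the
tunable parameters with their defaults, and what the test fixtures do
and do not demonstrate about real data.

## The graph model

All functions operate on an `igraph` object whose vertices carry unique
character labels (`name` attribute).  `as_netgraph()` and
`read_graph_file()` normalise input into this form: vertex order is
first-appearance order, self-loops and duplicate edges are removed when
`simplify = TRUE` (duplicate = same unordered pair if undirected, same
ordered pair if directed; the first weight seen is kept), and weights
must be strictly positive.  Reading a weighted file with
`weighted = FALSE` drops the weights with a warning.

Weight semantics differ by family and are fixed per measure:

* **distances** for the geodesic measures (distance family, shortest-path
  betweenness/stress/load): a heavier edge is a *longer* edge;
* **connection strengths** for the feedback family: weights enter the
  adjacency matrix;
* **capacities** for max-flow betweenness and **conductances** for the
  electrical measures (current-flow betweenness/closeness, information).

A measure that is undefined for directed graphs reduces the input to the
underlying undirected graph with a warning; one that ignores weights
drops them with a warning.  This keeps `centrality_score()` total over
the whole registry, which the batch job runner relies on.

## Distance family

With `d(v,u)` the geodesic out-distance, `R(v)` the set of vertices
reachable from `v` (excluding `v`), and `n` the vertex count:

* Freeman closeness `(|R(v)|/Σ_{u∈R(v)} d(v,u)) · (|R(v)|/(n−1))`.  The
  second factor is a disconnection penalty: on a connected graph it is 1
  and the formula is the classical closeness; across components it
  scales scores by the fraction of the graph reached, keeping them
  comparable.  The literature does not fix a disconnected convention;
  this one was chosen because it degrades continuously as components
  shrink.
* Latora (harmonic) closeness `Σ 1/d(v,u)` with `1/∞ = 0`; Dangalchev
  closeness `Σ 2^{−d(v,u)}` — both natively disconnection-tolerant.
* Barycenter `1/Σ d(v,u)`; Lin `(|R(v)|+1)²/Σ d(v,u)` (the `+1` counts
  the vertex itself, so the connected closed form is `n²/Σd`);
  eccentricity `1/max d(v,u)`; average distance `Σ d(v,u)/|R(v)|`;
  radiality `Σ (diam(G)+1−d(v,u))/(n−1)` with `diam(G)` the largest
  *finite* distance; decay `Σ δ^{d(v,u)}` (`δ = 0.5` by default, any
  value in (0,1)); geodesic K-path `|{u : d(v,u) ≤ k}|` (`k = 3`).
* Closeness vitality `W(G) − W(G−v)`, where the Wiener index `W` sums
  finite distances over unordered pairs (ordered pairs when directed).
* Centroid value `min_{w≠v} [γ_v(w) − γ_w(v)]` with `γ_v(w)` the number
  of vertices strictly closer to `v` than to `w`, the comparison running
  over `u ∉ {v,w}`.

A vertex with empty `R(v)` would divide by zero in
barycenter/Lin/eccentricity/average distance; it scores 0 with a
warning rather than raising, so that one isolated vertex cannot abort a
53-measure batch job.

## Neighborhood family

Degree and strength come in `total`/`in`/`out` variants.  Lobby is the
h-index of neighbor degrees; leverage is the mean of
`(k_v − k_u)/(k_v + k_u)` over neighbors.  The topological coefficient
averages shared-neighbor counts `J(v,u) = |N(v) ∩ N(u)| + [u ∈ N(v)]`
over all `u` sharing at least one neighbor with `v`, divided by `k_v`.
Semi-local centrality is the usual two-level sum of the number of
vertices within distance 2.  ClusterRank is
`10^{−c(v)} Σ_{u∈N_out(v)} (k_out(u)+1)` with `c` the local clustering
coefficient; on undirected graphs the out-neighborhood falls back to the
full neighborhood (documented fallback, since the measure was defined
for directed graphs).  Diffusion degree uses one global propagation
coefficient `λ` (default 1): `λ·k_v + λ·Σ_{u∈N(v)} k_u`; the literature
also allows per-vertex `λ`, which the package does not expose.

MNC is the order of the largest connected component of the subgraph
induced by `N(v)`; DMNC divides that component's edge count by its order
raised to `ε = 1.7` (the value used throughout the DMNC literature; any
value in (1,2) is accepted).  When two neighborhood components tie in
order, the denser one is used — a deterministic tie-break the original
definition leaves open.  Cross-clique connectivity counts maximal
cliques through `v` (pivoting enumeration, refused above 5·10⁵ cliques).
Burt's constraint follows the classical formula
`Σ_{j∈N(v)} (p_vj + Σ_q p_vq p_qj)²` on row-normalised tie strengths;
an isolated vertex scores 0 with a warning.

Graphlet degree counts, per vertex, the automorphism orbits (standard
numbering, orbits 0–14) of connected induced subgraphs on up to
`max_size = 4` vertices, via extension-tree enumeration; the scalar
score is the total number of graphlet incidences and the full orbit
matrix is exposed in `$extra$orbits`.  Size-5 orbits are excluded so
that the exhaustive-enumeration oracle remains cheap enough to verify
every count exactly.

## Feedback family

Spectral defaults are resolved at call time from the spectral radius
`λ_max`: Katz and alpha centrality use `α = 0.5/λ_max`, Bonacich power
`β = 0.9/λ_max`, and the Hubbell index scales `Aᵀ` by `0.5/λ_max` —
each guaranteeing the defining linear system `(I − αAᵀ)x = b` is
invertible.  Passing an `α ≥ 1/λ_max` raises an error that names the
spectral bound.  All power iterations (PageRank, LeaderRank, HITS,
SALSA) start from the uniform vector, so no randomness is involved;
they stop when the L1 residual drops below `tol = 1e-8` (configurable)
and raise after `max_iter` with the last residual.

Specific conventions:

* PageRank: damping 0.85, dangling vertices teleport uniformly, result
  normalised to sum 1.
* LeaderRank: a ground vertex is linked bidirectionally to every vertex,
  the walk is iterated to stationarity, and the ground's mass is folded
  back as `s_v + s_g/n`.
* HITS returns authorities as the primary score (hubs in `$extra$hub`),
  2-norm normalised; on undirected graphs authorities coincide with
  eigenvector centrality, which the tests assert.
* SALSA iterates the authority-side alternating walk per connected
  component of the bipartite hub/authority expansion and weights each
  component's stationary distribution by its share of the arcs; on that
  convention the score has the closed form `d_in(v)/|E|`, which serves
  as the independent oracle.  Undirected edges count as two arcs.
* Subgraph centrality is `diag(e^A)` via symmetric eigendecomposition.
* Laplacian centrality is the drop in Laplacian energy
  `E_L = Σ λ_i(L)² = trace(L²)` when `v` is removed, computed in closed
  form over weights and verified against literal removal.
* Entropy centrality follows the path-transfer model: a unit of flow
  starts at `v`, repeatedly moves to a uniformly chosen not-yet-visited
  neighbor, and stops when stuck; the score is the Shannon entropy (bits)
  of the stopping distribution.  Path enumeration is exact up to
  `exact_limit = 12` vertices and seeded Monte Carlo (`samples = 2000`)
  above it.  Several inequivalent "entropy centralities" exist; scores
  should not be compared across implementations.
* Community centrality projects each vertex onto the positive-eigenvalue
  subspace of the modularity matrix `B = A − kkᵀ/2m` and reports the
  vector magnitude `sqrt(Σ_j β_j U_vj²)`.  This, too, is one of several
  definitions sharing the name.

## Flow family

Three conventions apply family-wide: on undirected graphs each unordered
source–target pair is counted **once** (tools differ; the doubling
convention is fixed here and verified against the exhaustive oracle);
endpoints are never counted as interior vertices; `normalized = TRUE`
divides betweenness-type totals by `(n−1)(n−2)/s`, `s = 2` when
undirected.

* Betweenness uses Brandes' dependency accumulation; stress accumulates
  raw geodesic counts `σ_st(v)` with a path-count recursion on the
  shortest-path DAG; load routes a unit packet to every target with
  equal splitting at branch points (on trees load equals betweenness,
  which is asserted).
* Max-flow betweenness scores `Σ_{s<t} f_st(v)/maxflow(s,t)` where
  `f_st(v)` is the flow *forced through* `v`: the drop in s–t max-flow
  when `v` is removed.  (Flow through `v` in "a" maximum flow is not
  well-defined — maximum flows are not unique — so the package uses the
  removal formulation, which is.)
* Current-flow betweenness injects a unit current per source–sink pair
  and accumulates `½ Σ_u w_vu |p_v − p_u|` from potentials
  `p = L⁺(e_s − e_t)`; the raw sum over pairs is returned (the
  `normalized` flag averages it like the other betweenness variants).
* Current-flow closeness is `(n_c−1)/Σ_u (L⁺_vv + L⁺_uu − 2L⁺_vu)`
  within each component of size `n_c`.  Information centrality is
  computed independently through `(L + J)^{-1}` as the harmonic mean of
  the pairwise information `1/(c_vv + c_uu − 2c_vu)` over the `n_c − 1`
  companions; on this convention the two measures coincide exactly, and
  the equality (two genuinely different computations) is asserted to
  1e-8.
* Communicability betweenness compares `e^A` with and without `v`'s
  edges (row/column zeroed — edge deletion, not vertex deletion),
  normalised by `(n−1)² − (n−1)`.
* Markov centrality is `n_c/Σ_u m_uv` over mean first-passage times of
  the simple random walk, computed from the fundamental matrix per
  strongly connected component (with a warning when there is more than
  one).

Disconnected inputs are handled per component with a logged note;
current cannot flow between components, so this is the only meaningful
reading.

## Perturbation family

* Bottleneck builds one shortest-path tree per root `s` — BFS with the
  deterministic parent rule "first seen, lowest vertex order", since the
  literature's trees are ambiguous — and gives `v` one point per root
  whose tree routes more than `|T_s|/4` of its paths through `v`.
* Bridging centrality multiplies betweenness by the bridging coefficient
  `(1/k_v)/Σ_{u∈N(v)} 1/k_u`.
* EPC keeps each edge independently with probability
  `retention = 0.5` and averages, over `samples = 1000` seeded draws,
  the size of the component still containing `v` (the vertex counts
  itself, so at `retention = 1` the score is the component size).  One
  RNG stream seeded once drives all draws of a call; the seed parameter
  is part of the measure so batch outputs are byte-reproducible.
* Pairwise disconnectivity is the fraction of ordered reachable pairs
  destroyed by deleting `v` (pairs involving `v` count as destroyed).

## The essentiality workflow

`rank_vertices()` produces a total order, descending by default, with a
fixed tie-break (lexicographic label order in the C locale) so that
rankings — and everything downstream — are deterministic.
`topk_enrichment()` is the centrality–lethality readout:
`100·|top_k ∩ essential|/k`.

`aggregate_ranks()` merges many orderings into a consensus permutation
minimising the summed weighted distance.  "Spearman" distance is the
footrule `Σ_i |r₁(i) − r₂(i)|` (not squared), matching the rank
aggregation package this workflow mirrors; Kendall (discordant pairs)
is available.  Truncated top-m lists are extended over the union
universe by assigning every absent item the tied rank `m+1`, the
standard footrule extension.  Universes of at most 8 labels are solved
exactly by permutation search; larger ones use a genetic algorithm with
the mirrored defaults — population 100, crossover probability 0.4,
mutation probability 0.01, convergence window 15 generations — seeded
with the input orderings themselves plus random permutations, order
crossover, swap mutation and elitism.  The returned objective is always
recomputed from the consensus, and on small universes the tests require
the genetic search to hit the exhaustive minimum.  A consensus from a
stochastic search is a near-minimiser; re-running with another seed can
shift the objective by a fraction of a percent, which is why the seed
argument is mandatory in spirit and defaulted only for convenience.

## Jobs, formats and determinism

`run_job()` mirrors a server-style batch submission: sequential
zero-padded job ids, per-measure status/timing in `manifest.json`, a
CSV score table (vertex order = graph order, 12 significant digits) and
a score-annotated GML file.  One failing measure is recorded and the
rest continue.  The job seed is set before *every* measure, so outputs
do not depend on measure order and repeated runs are byte-identical —
the GML emitter is the package's own precisely so that no timestamp or
attribute-name mangling breaks that contract (GML attribute keys are
the measure ids sanitised to `[a-z0-9_]`).

Pajek support covers the `*Vertices/*Edges/*Arcs` sections and UCINET DL
the `fullmatrix` and `edgelist1` dialects — the minimal dialects that
cover demo-scale use; richer section types are rejected with a line
number.  The edge-list dialect is whitespace-separated with an optional
third weight column and `#` comments.

## What the fixtures do and do not show

The test suite is built on closed-form families (paths, cycles, stars,
complete graphs), seeded Erdős–Rényi and Barabási–Albert graphs, the
packaged 34-vertex karate club network, and the exhaustive atlas of all
996 connected graphs on up to 7 vertices.  Oracle suites compare every
implementation path against an independent route: Floyd–Warshall
distances, exhaustive geodesic enumeration, truncated matrix series,
literal vertex removal, Bron–Kerbosch clique enumeration, the full
`2^m` percolation expectation, and full permutation search.  These
sizes make exactness checkable; they say nothing about performance or
numerical behaviour at PPI scale (10³–10⁴ vertices), where the dense
matrix measures (current-flow, communicability, subgraph) cost `O(n³)`
memory-bound work, and the exact graphlet, entropy and max-flow
betweenness routines are the first to become expensive.  Scores on
synthetic graphs also exercise none of the noise, sampling bias and
annotation error of real interaction networks — a high enrichment on a
fixture validates the arithmetic, not the biology.

## Known limitations

Entropy and community centrality are variant-sensitive (several
definitions share each name); SALSA's component weighting makes it
degree-proportional, which is the documented closed form of this
convention; 5-vertex graphlet orbits, personalized PageRank, weighted
LeaderRank and edge centralities are out of scope; and the genetic
aggregation guarantees optimality only where the exhaustive check is
feasible.
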