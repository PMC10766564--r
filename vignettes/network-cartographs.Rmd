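---
title: "Interpretable network cartographs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable network cartographs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartonet)
```

## The problem cartonet addresses

In a force-directed network drawing, a node sits where the spring simulation
left it: its position reflects a compromise among esthetic forces, and there
is no way to read off *why* it is where it is, or to request that positions
encode a particular property. cartonet inverts that relationship. The user
chooses the node characteristic that positions should reflect; the package
turns that characteristic into a feature vector per node, converts the
`N x F` feature matrix into an `N x N` cosine-similarity matrix, embeds the
similarity matrix with t-SNE or UMAP, and assembles the coordinates into a
map. Nodes end up close together *because* they are similar in the chosen
sense — the layout is interpretable by construction.

The pipeline has four steps:

1. **Network input** — an edge list (`read_edge_list()`) or a model-network
   generator.
2. **Features** — one of five layout families (below) builds the `N x F`
   feature matrix.
3. **Similarity and embedding** — cosine similarity, then dimensionality
   reduction to 2D, 3D, or the unit sphere (`embed_similarity()`,
   `embed_sphere()`).
4. **Maps** — portraits use the coordinates directly; topographic maps add a
   per-node scalar as the z axis; geodesic maps place nodes on spherical
   layers or at annotation-driven radii.

## The five layout families

**Global** (`global_similarity()`). Each node's feature vector is its random
walk with restart (RWR) visiting-frequency profile: a walker seeded at node
$i$ restarts at $i$ with probability $r$ at each step and otherwise moves to
a uniformly random neighbour. With $W$ the column-normalized adjacency
matrix, the steady state has the closed form

$$\mathbf{p}_i = r\,(I - (1 - r)W)^{-1}\mathbf{e}_i,$$

computed once for all seeds by a single dense solve. Because $p_{i,j}$
decays smoothly with the network distance between $i$ and $j$, cosine
similarity of the profiles is a high-resolution proxy for pairwise network
distance, and the embedding reproduces the network's global shape.

**Local** (`local_similarity()`). Features are adjacency-matrix columns, so
similarity counts shared neighbours (normalized by degree). Nodes connected
to the same set of neighbours are maximally similar even when they are not
adjacent themselves; the layout therefore exposes bi- and multipartite
organization. On a bipartite lattice, opposite-parity nodes share no
neighbours and their similarity is exactly 0 — the layout splits the
network into two clusters.

**Importance** (`importance_similarity()`). Features are the 4-vector of
degree, closeness, betweenness and eigenvector centrality. Nodes of equal
structural importance — all nodes of a torus, each shell of a Cayley tree —
receive identical vectors and coincide in the layout.

**Functional** (`functional_similarity()`). Features are binary annotation
vectors (gene-disease associations, pathway memberships, any external
node-by-feature table). Node placement is driven purely by annotation
overlap; the network structure remains inspectable through the drawn links.

**Combined** (`combined_similarity()`). The RWR profile concatenated with
annotation columns scaled by a factor $m \ge 0$: $m = 0$ reproduces the
global layout exactly (zero columns do not change any inner product), and
as $m$ grows the annotation block dominates the cosine and the layout
approaches the functional one. $m$ is a continuous dial between structure
and function.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `restart_prob` (r) | 0.2 | RWR restart probability; smaller diffuses further, emphasizing global over local structure. 0.2 keeps both. |
| `method` | `"tsne"` | Reducer family; `"umap"` is the drop-in alternative. |
| `perplexity` | `min(100, floor((N-1)/3))` | t-SNE neighbourhood scale. |
| `n_neighbors` | `min(100, max(2, floor((N-1)/3)))` | UMAP analogue. |
| `init` | `"pca"` | Embedding initialization (see below). |
| `seed` | 42 | Governs every stochastic step; same config + seed = identical output. |
| `m` | 1 | Structure-function dial of the combined layout. |
| `z_scale` | 0.25 | Topographic z range as a fraction of the x-y bounding-box diagonal. |
| `r0`, `radial_scale` | 1, 0.5 | Geodesic base radius and radial span. |

Two of these deserve their rationale spelled out.

*Initialization and perplexity.* The similarity matrices here encode
**global** relationships, and the stated purpose of the global layout is to
reproduce pairwise network distances — precisely the regime where t-SNE's
default random initialization and small neighbourhoods are weakest. We
therefore initialize the optimization from the leading principal components
of the input (shrunk to the conventional sd of 1e-4) and use a generous
perplexity cap of 100. On the 1,000-node cubic grid this recipe is
seed-stable to three decimals, whereas random initialization at large
perplexity occasionally collapses a seed to a markedly worse optimum. Both
choices are exposed in `embedding_config()`.

*Centrality scaling.* Raw centralities live on incommensurate scales —
normalized betweenness is orders of magnitude smaller than degree — so one
column would otherwise dominate the cosine. Each column is divided by its
maximum (unit-max scaling). We deliberately do **not** min-max scale: a node
class that attains the minimum of all four centralities simultaneously (the
leaves of a Cayley tree) would be mapped to the zero vector, and the
zero-vector cosine convention (below) would assign similarity 0 *within*
that class, breaking the property that equally important nodes coincide.
Unit-max scaling preserves equality of profiles: every torus node maps to
`(1, 1, 1, 1)`. A `rescale = FALSE` flag restores the raw vectors.

## Numerical conventions and degenerate inputs

- **Zero-vector cosine.** A node with an all-zero feature vector (no
  annotations; an isolated adjacency column) has similarity 0 to every
  node, including itself. This keeps matrices finite and marks the node as
  "no information" rather than "similar to everything".
- **Connectivity.** RWR, closeness and the shortest-path benchmark are
  defined on connected graphs; disconnected input is rejected with an
  explicit error rather than silently restricted.
- **Eigenvector centrality** uses ARPACK with tolerance 1e-10 and up to
  10^4 iterations; equalities within a node class hold to ~1e-15 and all
  class-equality tests use a 1e-9 band.
- **Fully degenerate similarity** (all rows identical, e.g. an all-ones
  matrix) carries no layout information; the embedding returns the origin
  for every node with a warning instead of failing inside the reducer.
- **Euclidean post-normalization.** 2D/3D embeddings are centred and scaled
  to unit RMS radius, so topographic z scaling and map comparisons are
  well-defined regardless of the reducer's arbitrary output scale.
- **Sphere embeddings** are produced by running the 3D reduction, centring,
  and projecting radially onto the unit sphere — fully specified and
  backend-independent; a node landing exactly on the centroid (only
  possible in degenerate inputs) is sent to the north pole.
- **Pair order.** All-pairs quantities use the column-major lower-triangle
  order of unordered pairs, everywhere, so distance vectors align without
  reindexing.

## Benchmarking layouts, and which geometry to benchmark

`benchmark_layout()` compares, over all $N(N-1)/2$ unordered pairs, the
shortest-path distance $d^{SP}_{n,m}$ with the layout Euclidean distance
$d^{Euc}_{n,m}$, summarized by the Pearson correlation

$$r = \frac{\sum_{\{n,m\}} (d^{SP}_{n,m} - \mu^{SP})(d^{Euc}_{n,m} - \mu^{Euc})}
 {\sqrt{\sum_{\{n,m\}} (d^{SP}_{n,m} - \mu^{SP})^2 \sum_{\{n,m\}} (d^{Euc}_{n,m} - \mu^{Euc})^2}},$$

plus a per-distance quartile table that localizes distortion.

A caution on dimensionality that shaped our defaults: shortest-path
distances in a cubic grid are $L_1$ (Manhattan) distances in three
dimensions, and no arrangement of 1,000 points in the *plane* can make
Euclidean distances track them closely — the attainable correlation in 2D
is bounded well below what any reasonable 3D layout reaches, for any layout
algorithm. Distance-reproduction claims about intrinsically
three-dimensional networks are therefore benchmarked on 3D portraits in our
tests and acceptance script; 2D portraits of such networks remain useful as
pictures, but their correlation ceiling is geometric, not algorithmic. Even
in 3D the ceiling is below 1: $L_1$ distances are not exactly
Euclidean-embeddable in any dimension, so a perfect layout of the cube
cannot reach $r = 1$.

The force-directed baseline (`layout_force_directed()`) is igraph's
Fruchterman-Reingold implementation behind a thin adapter — an external
reference point, not part of the framework. 2,000 iterations is converged
for thousand-node lattices (doubling the budget does not change the
correlation to three decimals); the iteration count is recorded in the
map's provenance.

## What the synthetic annotation generator does and does not emulate

`generate_block_annotations()` plants the structure that makes functional
layouts informative in real biological data: groups of nodes (disease
modules) sharing a block of features, sparse background annotation, and an
optional fraction of pleiotropic nodes annotated to a second group — these
land between their two clusters in the layout, as multi-disease genes do.
The generator does **not** emulate ontology hierarchies (features are
independent, not nested), degree-annotation correlation (hubs are not more
annotated), or realistic annotation sparsity profiles. Passing the recovery
tests therefore shows that the functional pipeline separates planted
modules under noise; it does not by itself validate conclusions drawn from
any particular real annotation source.

Problem sizes in the test suite are chosen to exercise every code path at
desk scale: the 1,000-node cubic grid for the distance benchmark (the size
at which the published pair counts 4 at $d = 27$ and 46,852 at $d = 9$ are
exact combinatorial checks), lattices of tens of nodes for the algebraic
properties, and a 100-node, 4-group annotation fixture (within-group
annotation probability 0.9, background 0.01) for functional recovery,
where at least 90% of nodes must embed nearest their own group centroid
across seeds.

## Known limitations

- Dense linear algebra throughout: the RWR solve and similarity matrices
  are $O(N^2)$ memory; practical up to roughly $2 \times 10^4$ nodes, not
  interactome-concatenation scale.
- Layouts are only as meaningful as the chosen features; a visual cluster
  is a hypothesis generator, not a statistical test, and any pattern seen
  in a map needs confirmation outside the visualization.
- Geodesic layer assignment is an explicit input; the package does not
  decide which biological criterion should define the layers.
- The HTML export is a minimal self-contained viewer (rotatable point
  cloud), not a full interactive analysis environment.

## A compact worked example

```{r example, eval = FALSE}
g <- generate_cubic_grid(10)                       # N = 1,000
s <- global_similarity(g)                          # RWR (r = 0.2) + cosine
e <- embed_similarity(s, embedding_config(geometry = "space3d", seed = 42))
bench <- benchmark_layout(g, make_portrait(e))
bench$pearson_r                                    # ~0.95
subset(bench$by_distance, d_sp %in% c(9, 27))      # n = 46,852 and n = 4
```
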