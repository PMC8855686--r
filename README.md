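# hdgraph: holographic graph memory in hyperdimensional computing

`hdgraph` stores a whole graph — undirected, directed, or edge-weighted — in a
*single* high-dimensional integer vector, and gets it back out again. It is a
vector-symbolic (hyperdimensional computing) associative memory for graphs,
aimed at people studying brain-inspired memory models: how much structure fits
in one distributed representation, how retrieval degrades as it fills up, and
how simple iterative clean-up procedures push the capacity boundary.

## The model

Every node label `i` gets a random bipolar hypervector `H_i ∈ {−1,+1}^D`
(`D` in the thousands), drawn i.i.d. from a seeded codebook, so distinct
nodes are nearly orthogonal: `δ(H_k, H_l) ≈ N(0, 1/D)`, where
`δ(a, b) = a·b / D` is the similarity. Three exact integer operations build
structure: binding (componentwise product), bundling (componentwise sum, never
clipped), and an invertible permutation `ρ` (cyclic shift) that marks
direction.

* node memory: `M_i = Σ_j H_j` over the neighbors `j` of `i`
  (weighted: `M_i = Σ_j V_{w_ij} * H_j`, with `V_w` a deterministic
  suffix-flip encoding of `w ∈ [0,1)`);
* graph memory (undirected): `G = Σ_{(i,j)∈E} H_i * H_j`, one term per edge —
  identically `½ Σ_i H_i * M_i`;
* graph memory (directed): `G = Σ_i H_i * ρ(M_i)`.

Retrieval is thresholded similarity. The decision score of probe `H_B`
against a degree-`d` memory decomposes into signal + cross-term noise:
stored items score `R ~ N(1, (d−1)/D)`, absent ones `R ~ N(0, d/D)`, giving a
closed-form ROC, an SNR of `10·log10(D/(d−1))` dB, and the equal-error
threshold `T = √d/(√d+√(d−1))`. On top of this the package implements:

* **whole-graph reconstruction** by iterative noise cancellation — re-test
  every candidate edge against `G` minus the encoding of all other currently
  believed edges, until the edge indicator stabilizes;
* **node-memory reconstruction** (per-node neighbor sets) by the same
  subtract-believed-noise iteration;
* **memory refinement** — ±`H_i` corrections that drive the signal and noise
  score distributions apart, extending capacity of overloaded encodings;
* **graph matching** via the method of moments (`⟨Y²⟩` of a memory difference
  estimates the number of differing edges);
* **hypervector-native shortest path** — BFS where each frontier is a bundled
  memory and adjacency is tested by similarity;
* seeded synthetic generators (uniform fixed-edge-count graphs,
  chained-component graphs with controlled distances), capacity sweeps,
  plain-text serialization (`.hdv`), and a `graphd` CLI
  (`inst/cli/graphd`).

## Worked example

```r
library(hdgraph)

g  <- generate_random_graph(V = 30, E = 150, seed = 5)   # ground truth
cb <- generate_codebook(g$nodes, D = 3500, seed = 6)     # node hypervectors
G  <- encode_graph(g, cb)                                # one vector, D = 3500

estimate_edge_count(G)
#> [1] 145.6754                # second-moment estimate of |E| = 150

query_edge(G, g$edges$src[1], g$edges$dst[1], cb)$score
#> [1] 0.7668571               # signal 1 + cross-term noise; above T => present

rec <- reconstruct_graph(G, cb, reference = g)
rec$history
#>   iteration flips mismatches
#> 1         1   148          2
#> 2         2     2          0
#> 3         3     0          0
```

Reading: the direct thresholded pass (iteration 1) believes 148 edges and is
wrong about 2; one round of noise cancellation fixes both; the third pass
changes nothing, certifying convergence. The decoded edge set equals the true
150-edge graph exactly — a 30-node graph recovered from a single
3500-dimensional vector.

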