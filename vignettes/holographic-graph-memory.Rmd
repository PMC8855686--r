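---
title: "Holographic graph memory: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Holographic graph memory: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdgraph)
```

# The model and its assumptions

`hdgraph` is an associative memory for graphs built on three algebraic
operations over high-dimensional integer vectors. A codebook assigns each
node label an i.i.d. uniform bipolar hypervector `H_i` of dimension `D`.
Because random bipolar vectors in thousands of dimensions are nearly
orthogonal (pairwise similarity `~ N(0, 1/D)`), a sum of many of them keeps
each summand individually detectable by a dot product. Everything the package
does rests on that one statistical fact; all the rest is exact arithmetic:

* binding (`*`, componentwise product) is an involution on bipolar vectors,
  so `H_i * (H_i * x) = x` holds *exactly*, for any integer `x`;
* bundling (`+`) is plain integer addition and is never clipped or
  re-bipolarized, so similarity is exactly linear in each argument;
* the permutation `ρ` is a cyclic shift by one position, exactly invertible.

A node memory is the bundle of the node's (out-)neighbors; the graph memory
superposes one bound pair per edge. For undirected graphs we build
`G = Σ_{(i,j)∈E} H_i*H_j` directly as a sum over edges. The conventional
"half of `Σ_i H_i*M_i`" form is mathematically identical (every edge appears
at both endpoints), but the edge-sum form realizes the ½ factor without
fractional arithmetic; the node-memory form is retained only as a test
oracle. For directed graphs `G = Σ_i H_i*ρ(M_i)`: permuting the target side
makes the encoding non-commutative, preserving orientation, and no ½ factor
arises.

The model assumes: no self-loops (binding a vector with itself yields the
all-ones vector, which would bias every similarity), no duplicate edges
(duplicates in input collapse to one), and — for retrieval statistics — that
the dimension and edge counts are large enough for the central-limit
Gaussians to hold.

## Retrieval statistics

The decision score of probe `H_B` against an exact degree-`d` memory
decomposes into signal plus `d − 1` independent cross terms, each
`~ N(0, 1/D)`:

* stored item: `R ~ N(1, (d−1)/D)`;
* absent item: `R ~ N(0, d/D)`.

From these two Gaussians `signal_noise_model()` derives the theoretical ROC
(`roc_curve()`, normal tails via `pnorm`, no lookup tables), the SNR
`10·log10(D/(d−1))` dB (`snr_db()`), and the equal-error operating point

`T = √d / (√d + √(d−1))`  (`equal_error_threshold()`),

obtained by placing `T` the same number of standard deviations above the
noise mean as below the signal mean. `T` always lies in (0.5, 1] and falls to
0.5 as `d` grows. A commonly quoted `≈ 5·log(D/d)` SNR shorthand is treated
as a loose restatement of the exact formula above and is not implemented.
The degenerate `d = 1` case (zero signal variance) returns `T = 0.5` by
convention — any threshold in (0, 1) separates perfectly there.

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `D` | 4000 (CLI) | hypervector dimension. 4000 is the empirical sufficiency point for exact recovery of 100-edge graphs; 200 edges need ~6000. Cost is linear in `D`. |
| `T` | equal-error value | decision threshold. Derived per memory from `d̂ = 2Ê/V` (undirected; `Ê/V` directed) with `Ê` from `estimate_edge_count()`; fallback 0.5. |
| `max_iter` | 30 | iteration cap for noise-cancellation decoding. Within capacity, convergence takes < 15 iterations; divergence to a wrong fixed point is reported via the `converged` flag and mismatch history, never as an error. |
| `max_passes` | 50 | refinement sweep cap. Overloaded desk-scale encodings separate in a handful of passes. |
| edge weights | `[0, 1)` | validated strictly; a weight of exactly 1.0 is rejected rather than clamped, since the value codec reserves it for the base vector. |
| `trials` | 20/cell | capacity-sweep replication. Full-scale studies use up to 1000; 20 keeps sweeps desk-sized and is overridable. |

# Numerical conventions

* **Similarity** is `a·b/D`, *not* cosine similarity, including for integer
  bundles. Dividing by `D` only is what makes the score of a bundle equal
  the sum of its members' scores, which the Gaussian decomposition and the
  refinement arithmetic (`±H_i` moves a score by exactly ±1) depend on.
* **Value codec rounding**: a weight `a` flips the suffix of the base vector
  starting at component `round(a·D)`, with round-half-to-even (base R
  `round`). Round trips therefore return exactly `round(a·D)/D`, and nearby
  weights give correlated vectors with similarity
  `1 − 2·(round((a+ε)D) − round(aD))/D`, exactly.
* **Threshold ties**: scores live on a `1/D` lattice, so a score can equal
  `T` exactly. Refinement treats a tie as a misprediction (updates on
  `R ≤ T` for edges, `R ≥ T` for non-edges), which guarantees the converged
  state is *strictly* separated. Retrieval queries use strict `R > T`.
* **Refinement sweep order** is deterministic: probe nodes `i` in codebook
  (sorted-label) order, memories `j` likewise; within one probe the updates
  to different memories are independent, so they are applied as a batch.
* **After refinement** the graph memory is rebuilt as `Σ_i H_i*M_i^refined`
  *without* halving — refined memories are no longer symmetric edge sums, so
  the halved form is not well defined. The memory's `kind` records
  `refined-`, and `query_edge()` halves the raw score of refined undirected
  memories to compensate for the doubled edge count. Decoding refined
  memories beyond such direct queries is out of scope.
* **Noise cancellation at edge granularity**: the printed recursion for
  node-memory re-estimation, taken literally against the halved graph
  memory, double-subtracts shared edges. The implementation instead
  subtracts each believed edge hypervector exactly once (all believed edges
  not incident to the node in question), which is algebraically what the
  recursion intends and is exact when the beliefs are correct: if the
  believed edge set equals the truth, the residual `G − G_k` plus the
  re-added incident edges is exactly the node's memory. For the same reason
  the true edge indicator is a fixed point of whole-graph reconstruction.
* **Jacobi, not Gauss–Seidel**: each reconstruction iteration builds the new
  indicator from a frozen copy of the previous one, in lexicographic pair
  order, so results are order-independent and deterministic.
* **Cleaned-up estimates**: node-memory reconstruction re-thresholds from
  exact integer bundles of currently believed neighbors instead of carrying
  raw noisy vectors across iterations; raw iteration is vulnerable to drift
  since its converged vectors retain accumulated error.
* **Codebook order**: labels are sorted in the codebook, making every
  encoding independent of edge-file row order. Seeded generation never
  disturbs the caller's RNG stream (seeds are applied locally and the state
  restored).

# Design choices where the design was genuinely open

* **Permutation**: a cyclic shift rather than a stored random permutation —
  invertible, composable by exponent arithmetic, and metadata-free for
  serialization. Only `ρ¹` is ever needed by the encodings here; a seeded
  random permutation is accepted as an optional encoding parameter and
  recorded in the memory metadata.
* **Refinement scope**: the update rule adds whole node hypervectors and has
  no published weighted analogue (`± V_w*H_j` would be a guess), so weighted
  memories are rejected with a labeled error rather than silently handled.
* **Refinement threshold**: nothing fixes whether the refinement `T` equals
  the retrieval threshold; the package defaults both to the same equal-error
  value.
* **Graph matching in unbind mode**: when node memories are unbound from two
  graph hypervectors that share a codebook, the unbinding noise of every
  *shared* edge cancels exactly in the difference `H_a*(G − G′)`. The
  residual noise power per component is the number of differing edges — not
  the per-graph edge count — so the package estimates the total difference
  directly as `mean((G − G′)²)`, the method-of-moments estimator applied to
  the memory difference itself, and corrects per-node estimates by the
  expected non-incident share of that total (floored at 0). Exact-memory
  mode remains the default and the unbiased reference path.
* **Shortest-path memories**: level expansion uses node memories
  reconstructed from the graph hypervector by default (the fully holographic
  route); exact memories can be supplied. Frontier bundles accumulate noise
  with variance (total frontier degree)/D, which is why success decays with
  distance; the package surfaces the discovered levels for diagnosis but
  deliberately does not rescale the threshold. Backtracking picks uniformly
  at random (seeded) among qualifying predecessors; if interference leaves
  none above threshold, the best scorer is taken so a discovered target
  always yields a path.
* **Weighted shortest path** is intentionally not implemented beyond
  per-pair weight queries: thresholding weighted similarities yields a
  stochastic, weight-biased notion of reachability rather than a shortest
  path, so it is left out rather than given misleading semantics.

# What the synthetic generator emulates — and what it does not

`generate_random_graph()` draws exactly `E` distinct edges uniformly from all
possible edges on `V` labeled nodes — equivalently a complete graph with a
uniformly chosen deletion set. This matches the evaluation protocol of the
capacity experiments: fixed edge count, uniform edge placement, i.i.d.
uniform weights on `[0, 1)` when weighted. `generate_chained_graph()` builds
disjoint random components joined consecutively at one anchor node each, so
anchor `k` sits at distance `k − 1` from anchor 1 — the controlled-distance
construction for shortest-path evaluation; the construction is certified by
a BFS check at generation time. Consecutive joining is the only reading
under which the construction produces pairs at controlled distances 1…d;
joining *all* anchors pairwise would make every anchor distance 1.

Two caveats. First, the printed full-scale chain parameters (components of
21 vertices and 270 edges) are infeasible for simple graphs — 21 vertices
admit at most 210 edges — so the package's tests use 21 vertices and 180
edges, dense but feasible; the generator rejects infeasible configurations
loudly. Second, real relational data is neither uniform nor degree-balanced:
heavy-tailed degree distributions concentrate cross-term noise on hub nodes,
so a green capacity test here does *not* establish the same capacity on
scale-free graphs. The Gaussian model predicts per-node behavior through the
node's own degree, which is the right lens for such data, but the sweeps
only sample the uniform world.

Similarly, "dimension drop" noise zeroes a uniformly chosen set of
components (removing their signal *and* noise contribution — the reading
consistent with drop-out robustness, as opposed to sign flips, which inject
noise). Hardware-style correlated failures are not modeled.

# What a green test establishes

The acceptance experiments are desk-scale: graphs of 100–200 edges,
dimensions 2000–10000, 10–20 seeds. They establish that the implementation
realizes the model's predictions in the regime where the model says decoding
should succeed (and fails visibly where it should fail — the overloaded
D = 500 / 300-edge regime is asserted to diverge). They do not reproduce
full-scale experiments (e.g. refinement of a 100,000-edge memory, whose
dimension is unstated); the refinement acceptance check is explicitly a
scaled-down analogue: a 150-edge graph whose node memories are *unbound from
the graph hypervector* at D = 2000, which is the regime where initial signal
and noise scores genuinely overlap at `T = 0.5` (exact node memories at that
scale are already separated by ~7 standard deviations, and refining them
would be a no-op).

# Known limitations

* Whole-graph reconstruction scans all `V(V−1)/2` candidate pairs per
  iteration; memory and time scale as `O(V²D)`. Fine for hundreds of nodes,
  not for millions.
* Weighted whole-graph reconstruction is not provided (no published
  procedure); weights are recoverable per queried pair only.
* Incremental edge insertion/deletion and decay dynamics are out of scope.
* The capacity model treats cross terms as independent Gaussians; at very
  small `D` or very dense graphs the discrete lattice and dependence between
  scores make the tails heavier than predicted — visible as the sweep's
  divergence regime.
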