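---
title: "Complex detection in noisy PPI networks: the model behind pewcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex detection in noisy PPI networks: the model behind pewcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pewcc)
```

## The problem

High-throughput interaction screens (yeast two-hybrid, affinity
purification) produce protein–protein interaction (PPI) networks with
substantial false-positive and false-negative rates — false-positive rates
above 50% have been reported for two-hybrid screens. Protein complexes
appear in such networks as dense subgraphs, but clique-style detectors
degrade quickly when spurious edges blur the boundary between a complex and
its surroundings. `pewcc` therefore splits the task in two: first decide
which interactions are credible, then look for near-cliques only in the
cleaned topology.

## Stage 1: interaction reliability (PE-measure)

Model the network as an undirected simple graph $G = (V, E)$ over protein
IDs. Each edge gets an initial reliability $p^{(0)}_{ij} = 0.5$ — an
uninformative prior that an observed interaction is genuine. Reliability is
then updated synchronously for $k$ iterations:

$$p^{(k)}_{ij} \;=\; 1 - \prod_{l \,:\, (i,l) \in E,\ (j,l) \in E}
  \bigl(1 - p^{(k-1)}_{il}\, p^{(k-1)}_{jl}\bigr).$$

The product runs over the common neighbors of $i$ and $j$: each neighbor
$l$ "supports" the edge with probability $p_{il} p_{jl}$, and the edge is
credible if at least one common neighbor supports it. An edge in no
triangle has the empty product and drops to exactly 0 after one iteration,
permanently. All values provably stay in $[0, 1]$ and the matrix stays
symmetric; both are asserted as property tests on random graphs.

Only the *previous* iteration's values appear on the right-hand side
(a Jacobi-style sweep), so the result does not depend on edge enumeration
order.

After scoring, each protein $i$ averages its incident reliabilities,
$\bar w_i = \sum_{l \in N_i} p_{il} / |N_i|$, and an edge $(i, l)$ is
removed when $p_{il}$ is *strictly* below the average of either endpoint.
All averages are computed on the unfiltered network and removals applied
at once; ties survive, so a uniformly weighted network loses nothing.
Judging from either endpoint is deliberate: a per-protein scan that touches
every node removes an edge as soon as one side considers it below par. The
complementary both-endpoint variant can be emulated by filtering manually
from `node_average()`; we expose the either-endpoint rule because it is the
one that makes the five-protein worked example remove its noise edge.
Proteins are never deleted — they may become isolated, which downstream
detection simply ignores.

Two classical common-neighbor scores are included for comparison and
ablation: the CD-distance
$1 - 2|N_u \cap N_v| / (|N_u| + |N_v|)$ and the degree-adjusted AdjstCD
with its iterated form (`adjstcd_score()`), whose first step equals plain
AdjstCD when the running average weight is seeded from the adjacency
indicator. The iterated-AdjstCD filter reuses the same per-node-average
removal rule as the PE filter, since no separate threshold is established
for it.

`k = 2` is the default number of iterations for both scorers; more
iterations change the scores slightly but not the below-average/above-
average classification that drives filtering in any meaningful way.

## Stage 2: detection by weighted-clustering-coefficient peeling

For each seed protein $v_i$ with at least 3 neighbors, form the
*neighborhood graph*: the subgraph induced on its neighbors, the seed
itself excluded. With $N_i$ members and $N_{3cliques}$ member edges (each
member edge closes a triangle through the seed), the weighted clustering
coefficient is

$$c_i = \frac{2\, N_{3cliques}}{N_i^2 (N_i - 1)} \;\le\; \frac{1}{N_i}.$$

The $1/N_i$ bound (a member graph has at most $N_i (N_i - 1)/2$ edges)
means the score rewards *small and dense* member sets, which is what makes
greedy shrinking meaningful. The member with the lowest member-graph
degree is removed (with its edges), $c_i$ recomputed, and the loop stops
at 3 members. The step with the highest $c_i$ — the initial, un-peeled
neighborhood included — is the *core*; the seed is added back to it. On a
member triangle the formula yields $c_i = 1/3$, the maximum any 3-member
set can achieve; we implement the formula as stated and note that the
method cannot emit complexes of fewer than 4 proteins (core of 3 members
plus the seed) by construction.

Finally, every member of the *original* neighborhood that interacts with
strictly more than a fraction $t$ of the core proteins (core size counts
the seed) rejoins, in a single pass against the pre-rejoin core — joined
proteins do not recruit further. Complexes from all seeds are collected,
those below `min_size` dropped, and exact duplicates removed keeping the
first seed in ID order. Overlapping, non-identical complexes are all kept:
the method does no overlap merging.

Numerical choices where the procedure is genuinely open:

* **Tie-breaking.** Minimum-degree ties are resolved lexicographically by
  default (reproducible; the six-protein worked example reaches the same
  final complex under either tied choice), with `tie_break = "random"` plus
  `rng_seed` reproducing the randomized variant. A consequence worth
  knowing: with lexicographic ties, detection commutes with *order-
  preserving* renamings of the proteins, not with arbitrary ones — an
  arbitrary renaming can change which tied member is peeled first.
* **$c$ argmax ties** prefer the earliest (largest) member set, keeping
  more proteins when density is equal.
* **Weights are not used inside $c_i$**: the coefficient is purely
  topological, so detection runs on the filtered topology and ignores the
  reliability values carried on surviving edges.
* Seeds of degree below 3 are skipped — there is no peelable neighborhood.

Defaults `t = 0.3`, `min_size = 4`, `k = 2` are the standard operating
point of the method; raising `t` mainly multiplies near-duplicate
predictions (hurting precision) without improving accuracy.

## Evaluation metrics

Predictions $P = \{K_1 \dots K_m\}$ are scored against a reference catalog
$R = \{R_1 \dots R_n\}$ with the Jaccard match score
$|K \cap R| / |K \cup R|$; $K$ matches $R$ when the score reaches
$\alpha$ (0.25 and 0.5 are the conventional thresholds). From the
$n \times m$ confusion matrix $t_{ij} = |R_i \cap K_j|$:

* complex-level recall, precision, and their harmonic mean F1;
* clustering-wise sensitivity $Sn = \sum_i \max_j t_{ij} / \sum_i |R_i|$,
  positive predictive value
  $PPV = \sum_j \max_i t_{ij} / \sum_j \sum_i t_{ij}$, and their geometric
  mean $Acc$ (the identity $Acc^2 = Sn \cdot PPV$ is asserted to
  $10^{-12}$);
* the maximum matching ratio (MMR): the total weight of a maximum-weight
  one-to-one assignment between references and predictions, divided by
  $n$. Zero-score pairs get no edge in the bipartite graph and can never
  be matched. The assignment step uses igraph's weighted bipartite
  matching and is cross-checked in the tests against an exhaustive
  branch-and-bound oracle for catalogs up to $6 \times 6$.

Empty catalogs yield zeros with a message rather than errors, so pipelines
on degenerate inputs run to completion.

## What the synthetic benchmarks emulate

`planted_complex_network()` plants `n_complexes` disjoint groups of 5–8
proteins, wires each within-group pair with probability `p_in = 0.9`,
embeds them among 40 background proteins with sparse background and
cross-group wiring (`p_out = 0.01`), and can inject uniformly random
spurious edges among the existing proteins (`add_random_edges()`), mirroring
the random-noise-injection protocol used to probe robustness. The 40
background proteins give roughly one background protein per planted one —
enough sparse context that noise edges can form misleading triangles —
while keeping a full 10-seed × 2-noise-level experiment around a minute;
those are this package's own problem sizes for the desk-scale experiment.

What these benchmarks do *not* emulate: scale-free degree distributions,
overlapping or nested complexes, correlated (experiment-batch) noise, and
missing interactions inside true complexes beyond the $1 - p_{in}$ dropout.
Passing the robustness tests therefore shows the filter beats no-filter
under uniform random insertion noise, not that absolute scores transfer to
real interactome data.

The headline robustness property checked in the test suite: at noise
levels of 2× and 4× the clean edge count, the F1 (at $\alpha = 0.5$) of
PE-filtered detection exceeds unfiltered detection in at least 7 of 10
generator seeds — in practice it wins in all 10 at both levels.

## Degenerate inputs and edge cases

* Empty networks and empty catalogs flow through every stage (empty
  outputs, metrics of 0 with a message).
* Self-loops are dropped and duplicate edge-list lines collapsed (last
  weight wins) at read time, with counts reported.
* Isolated proteins have no reliability average and no entry in
  `node_average()`; both-isolated pairs make `cd_distance()` error since
  its denominator vanishes.
* `wcc()` requires 2 members, `peel()` 3; callers skip smaller seeds.

## Known limitations

* Complexes of 3 or fewer proteins are out of reach by construction.
* No overlap-aware post-processing: heavily overlapping predictions are
  reported as-is (MMR is the overlap-tolerant metric for that situation).
* The reliability stage uses topology only; external evidence (expression,
  localization, sequence) is outside this package's scope.
* The dense per-iteration update matrices make the scorers comfortable up
  to a few thousand proteins; genome-scale networks work but take minutes
  rather than seconds.
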