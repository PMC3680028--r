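# pewcc

Protein complex detection from noisy protein–protein interaction (PPI)
networks, for computational biologists working with interactome data from
high-throughput screens. Such screens carry high false-positive rates, and
complex detectors that hunt for dense subgraphs degrade quickly on spurious
edges. `pewcc` implements the two-stage PEWCC approach:

1. **Reliability (PE-measure).** Every edge starts at probability 0.5 and
   is iteratively re-scored by how strongly its common neighbors support
   it,

   $$p^{(k)}_{ij} = 1 - \prod_{l \in N_i \cap N_j}
     \bigl(1 - p^{(k-1)}_{il}\,p^{(k-1)}_{jl}\bigr),$$

   then every edge scoring strictly below the average of either endpoint's
   incident edges is removed. Edges in no triangle score exactly 0 and
   always go. CD-distance and the iterated AdjstCD weighting are included
   as alternative scorers.

2. **Detection (weighted clustering coefficient).** For each seed protein,
   the subgraph induced on its neighbors is peeled — the lowest-degree
   member removed repeatedly down to 3 members — and the member set
   maximizing

   $$c_i = \frac{2\,N_{3cliques}}{N_i^2\,(N_i - 1)}$$

   (member edges = triangles through the seed) becomes the core; proteins
   interacting with more than a fraction `t` of the core rejoin. Defaults:
   `k = 2` iterations, `t = 0.3`, minimum complex size 4.

The package also ships the standard evaluation suite (Jaccard match score,
complex-level recall/precision/F1, clustering-wise Sn/PPV/Acc, maximum
matching ratio), tab-separated edge-list and one-complex-per-line catalog
I/O, planted-complex benchmark generators with random-noise injection, and
a command-line front-end (`exec/pewcc`).

## Worked example

Plant 10 complexes of 5–8 proteins among 40 background proteins, inject
400 random spurious edges, and run the full pipeline against the known
truth:

```r
library(pewcc)

b <- planted_complex_network(rng_seed = 7, noise_edges = 400)
b
#> planted_benchmark: 10 complex(es), 108 proteins, 635 interactions (seed 7 )

res <- run_pipeline(b$network, refs = b$truth, method = "pe", alpha = 0.5)
#> config: method=pe k=2 t=0.3 min_size=4 alpha=0.5 tie_break=lex rng_seed=NULL
#> reliability filter (pe, k=2): removed 394 of 635 edges
#> detected 49 complex(es)
#> evaluation: F1=0.957 Acc=0.934 MMR=0.986

print(res$report, row.names = FALSE)
#>  alpha n_ref n_pred matched_ref matched_pred rec      prec        f1        sn
#>    0.5    10     49          10           45   1 0.9183673 0.9574468 0.9852941
#>        ppv       acc       mmr
#>  0.8854489 0.9340383 0.9857143
```

Reading the report: the filter discarded 394 of 635 edges (the injected
noise is mostly triangle-free, so it scores near 0); every one of the 10
planted complexes is recovered at Jaccard ≥ 0.5 (`rec = 1`), 45 of the 49
predictions match a true complex (`prec = 0.92` — PEWCC keeps overlapping
near-duplicate predictions rather than merging them), and the optimal
one-to-one assignment recovers 98.6% of the possible match weight
(`mmr`). Running the same call with `method = "none"` shows what the
reliability stage buys: F1 drops sharply once noise is left in place.

The same pipeline from a shell:

```sh
exec/pewcc simulate --complexes 10 --noise 400 --rng-seed 7 -o net.tsv --truth truth.txt
exec/pewcc detect --method pe -t 0.3 net.tsv -o predicted.txt
exec/pewcc evaluate --refs truth.txt --preds predicted.txt --alpha 0.5
```

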