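Package: pewcc
Title: Protein Complex Detection from Noisy Protein-Protein Interaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects protein complexes in undirected protein-protein
    interaction (PPI) networks with the two-stage PEWCC approach: a
    probabilistic assessment of interaction reliability (the PE-measure,
    with CD-distance and iterated AdjstCD as alternative scorers) that
    removes edges scoring below their endpoints' averages, followed by
    complex detection through iterative lowest-degree peeling of seed
    neighborhood graphs maximizing a weighted clustering coefficient and a
    rejoin step. Ships the standard evaluation suite for predicted
    complexes (Jaccard match score, complex-level recall/precision/F1,
    clustering-wise Sn/PPV/Acc, maximum matching ratio), readers and
    writers for tab-separated edge lists and one-complex-per-line
    catalogs, and generators for planted-complex benchmarks and
    random-edge noise experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
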