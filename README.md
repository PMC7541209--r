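# netpharm

Network-pharmacology analysis of protein–protein interaction networks
(PPINs) in R.

Multi-target natural products act through sets of target proteins whose
joint behavior is best read off the interactome: which interactions around
the targets are topologically credible, which network neighborhoods form
functional modules, and which pathways those modules share. `netpharm`
implements that analysis as a tested, reusable pipeline:

1. **Network construction** — read a STRING-style scored edge list
   (`protein1 protein2 combined_score`, scores 0–1000), drop low-confidence
   interactions (default: keep `combined_score >= 300`), and build the
   *true* PPIN with nodes labeled `TARGET` or `INTERACTOR`. A contrast
   *false* PPIN is built from target-incident non-edges (pairs with no
   recorded interaction), by default sampled to the same size as the true
   edge set so downstream two-sample comparisons are balanced.
2. **Edge attributes** — four link-prediction scores per node pair, computed
   on the true topology. For a pair (u, v) with neighborhoods N(·)
   excluding u and v themselves:
   Jaccard `|N(u) ∩ N(v)| / |N(u) ∪ N(v)|`; preferential attachment
   `deg(u)·deg(v)`; common neighbors `|N(u) ∩ N(v)|`; resource allocation
   `Σ_{z ∈ N(u) ∩ N(v)} 1/deg(z)`.
3. **Node attributes** — degree, closeness (component-scaled
   Wasserman–Faust), eigenvector (power iteration, unit norm), betweenness
   (normalized by `(N−1)(N−2)/2`), local clustering coefficient, and
   per-component eccentricity.
4. **Attribute selection** — Pearson correlations of the STRING score
   against each edge attribute; Welch two-sample *t* tests (Bonferroni,
   m = 4) ranking the edge attributes by true-vs-false discrimination; a
   ridge-logistic + random-forest importance ranking of the node attributes
   with stratified cross-validated ROC area.
5. **Refinement** — percentile pruning of the true PPIN: remove edges with
   Jaccard score strictly above its 75th percentile, then nodes with
   closeness strictly below its 25th percentile, then isolated nodes.
6. **Clustering** — a from-scratch Markov Cluster (MCL) algorithm on the
   column-stochastic transition matrix (expansion 2, inflation 2.0,
   self-loops weight 1), yielding a hard partition of proteins into
   modules.
7. **Enrichment** — upper-tail hypergeometric overrepresentation of each
   cluster against GMT pathway gene sets,
   `P(X ≥ k), X ~ Hypergeom(N, K, n)`, with Benjamini–Hochberg FDR across
   the full family and a report of pathways significant in ≥ 2 and ≥ 3
   clusters — the cross-cluster overlaps that suggest synergistic action.

A fully seeded synthetic-data module generates planted-community interaction
networks, target lists, and pathway collections with known ground truth, so
every stage is testable at desk scale without external services.

## Worked example

```r
library(netpharm)

d <- tempfile()
paths <- write_synthetic_inputs(d)   # links.txt, targets.txt, pathways.gmt
cfg <- pipeline_config(paths$links, paths$targets, paths$gmt,
                       out_dir = file.path(d, "out"), seed = 1)
report <- run_pipeline(cfg)
```

```
[netpharm] read: 817 records, 805 kept at min_score=300
[netpharm] build: true 120 nodes / 805 edges; false 805 edges
[netpharm] attributes: 1610 edge rows, 240 node rows
[netpharm] selection: edge winner jaccard, node winner closeness (AUC 1.000)
[netpharm] prune: 90 nodes / 419 edges remain
[netpharm] cluster: 7 clusters
[netpharm] enrich: 5 significant of 193 tests; 1 pathway(s) shared by >= 3 clusters
```

Reading the log: of 817 synthetic interaction records, 805 score at least
300 and form a 120-protein network. The Welch ranking finds the Jaccard
score the most discriminating edge attribute between true and false edges,
and closeness centrality tops the classifier importance for nodes (the
cross-validated ROC area of 1.0 says true- and false-network node rows are
perfectly separable here). Pruning leaves a 90-node, 419-edge network; MCL
splits it into 7 modules; 5 cluster–pathway pairs are significant at
FDR 0.05, and one pathway — the planted cross-community pathway
`PW_SHARED` — is enriched in three different clusters at once.

All stage outputs (`edges.tsv`, `edge_scores.tsv`, `node_scores.tsv`,
`selection.tsv`, `pruned.tsv`, `clusters.tsv`, `enrichment.tsv`,
`overlap.tsv`, `report.json`, `run.log`) are written under `out_dir`.

To analyse real data, point `pipeline_config()` (or a YAML config and the
CLI wrapper in `inst/scripts/netpharm.R`) at your own STRING-format links
file, target list, and GMT gene sets.

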