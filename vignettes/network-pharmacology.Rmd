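---
title: "Methods: PPIN topology, Markov clustering, and pathway overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPIN topology, Markov clustering, and pathway overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

This vignette is the package's account of its methods: the models and
statistics each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical and design choices made where the design was
genuinely open.

## The analysis

The object of study is a protein–protein interaction network (PPIN) around
a set of *target proteins* — proteins predicted to be bound by a compound of
interest — embedded among their *interacting proteins* from a scored
interaction database. The analysis asks three questions in sequence. First,
which topological statistics distinguish real interactions from
non-interactions? Second, after thinning the network with those statistics,
what modular structure does it have? Third, which biological pathways do the
modules share — the signature of a multi-target, synergistic mechanism.

### True and false networks

The true PPIN is an undirected simple graph: one node per protein mentioned
in the (score-filtered) interaction records, one edge per recorded pair.
Interaction confidence scores are integers on the STRING 0–1000 scale; the
default filter keeps scores of at least 300, removing only low-confidence
records (a record scoring exactly 300 is kept).

The false PPIN is a *negative contrast class*: its "edges" are pairs with at
least one target endpoint that are **not** recorded interactions.
Restricting to target-incident pairs keeps the contrast relevant to the
target neighborhood; pure interactor–interactor non-edges are excluded. The
complete non-edge set is available (`n_false_edges = "all"`) but grows as
|targets| × |nodes|; the default draws a uniform sample the same size as the
true edge set, because the downstream Welch tests and classifiers behave
best with balanced classes and the comparison is then symmetric. The sample
is seeded and reproducible.

### Edge attributes (link-prediction scores)

All four scores are computed on the *true* network's topology — a candidate
pair is judged by the observed interactome around it, so a false pair
contributes no edge of its own. With N(·) a neighborhood excluding both
members of the pair under evaluation:

* **Jaccard**: |N(u) ∩ N(v)| / |N(u) ∪ N(v)| — shared-neighbor fraction.
  Excluding the endpoints from the union matters for adjacent pairs: each
  edge of a triangle scores 1 (the endpoints share their single outside
  neighbor), rather than having the mutual membership of u and v dilute the
  union. The convention only affects the union; the intersection can never
  contain an endpoint in a simple graph.
* **Preferential attachment**: deg(u)·deg(v).
* **Common neighbors**: |N(u) ∩ N(v)|.
* **Resource allocation**: Σ 1/deg(z) over shared neighbors z. A shared
  neighbor is adjacent to both endpoints, so deg(z) ≥ 2 and the sum is
  always defined; this is asserted, not guarded.

### Node attributes

Six per-node statistics: degree; closeness; eigenvector centrality;
betweenness; local clustering coefficient; eccentricity. The pruned and
false networks are routinely disconnected, so the disconnected-graph
conventions matter and are chosen to keep every value comparable across
networks:

* **Closeness** uses the component-scaled (Wasserman–Faust) normalization
  `((n_c − 1)/(N − 1)) · ((n_c − 1)/Σ d)` with n_c the node's component
  size; values stay in [0, 1] and shrink for small components. Isolated
  nodes get 0.
* **Betweenness** is Brandes shortest-path betweenness, endpoints excluded,
  divided by `(N − 1)(N − 2)/2`; graphs with fewer than three nodes get 0.
* **Eigenvector centrality** is the principal eigenvector of the adjacency
  matrix, non-negative, unit Euclidean norm, computed by power iteration
  (tolerance 1e-8 in max-norm, budget 1000 iterations, uniform start;
  non-convergence is an error naming the budget). Iteration runs on A + I:
  the unit diagonal shift leaves eigenvectors unchanged but breaks the
  ±λ magnitude tie of bipartite components that makes plain power iteration
  oscillate. On disconnected graphs the dominant eigenvalue can be
  degenerate across components (e.g. two isomorphic components); the tie is
  broken toward the largest such component, with a warning, and all other
  components get 0.
* **Eccentricity** is the largest shortest-path distance within the node's
  own component; isolated nodes get 0.
* A graph with no edges has no principal direction; the attribute table
  then reports eigenvector centrality 0 for every node.

### Attribute selection

Pearson correlations relate the database confidence score to each
topological edge attribute on true edges. Discrimination between true and
false rows uses **Welch's unequal-variance t test** rather than the pooled
test: the topological scores of true and false groups have grossly unequal
spreads, and Welch is the safe default there. Four tests (one per edge
attribute) are Bonferroni-adjusted — conservative and exact for m = 4 —
with Benjamini–Hochberg available as an option. Ranking is by ascending
adjusted p, ties broken by descending |t|; if every adjusted p is 1 the
ranking is flagged inconclusive.

Node attributes are ranked by two classifiers with complementary biases: a
ridge-penalized logistic model (penalty weight 1.0, features standardized;
importance = |standardized coefficient|) and a 200-tree random forest
(importance = mean impurity decrease). Attributes are ranked within each
method and aggregated by mean rank, ties broken by the linear importance.
Separability is summarized by a stratified 5-fold cross-validated ROC area
of the *combined* model — the average of the two classifiers' fold
probabilities — which avoids privileging either inductive bias. All
randomness (folds, bootstrap) is seeded.

The rows of the two node tables refer to the same protein identifiers
evaluated in two topologies, but the tests and classifiers treat rows as
independent samples; this mirrors how such comparisons are usually run, and
the cross-validated ROC area should be read as separability of the two
attribute distributions, not as a generalization claim.

### Refinement (percentile pruning)

Thresholds are percentiles of the *un-pruned* true network's own attribute
distributions, computed once before any removal: edges with Jaccard score
strictly **above** the 75th percentile are removed, then nodes with
closeness strictly **below** the 25th percentile (with their incident
edges), then nodes left isolated. The strict inequalities mean tied values
at the cutoff always survive, and with all-distinct values the two rules
remove a quarter of the edges and flag a quarter of the nodes (±1).
Percentiles use linear interpolation (rank position `(q/100)(n−1)` on the
sorted values), the common default in numerical software. Re-applying the
operation with the same precomputed cutoffs is idempotent.

Two open choices are worth flagging. The order of operations (edges, then
nodes, then cleanup) and the use of pre-pruning closeness values for the
node rule are conventions of this package; recomputing closeness after edge
removal would remove slightly different nodes. And removing *high*-Jaccard
edges is deliberate and faithful to the workflow this package implements,
even though Jaccard is the attribute on which true edges score high — the
rule thins the densest neighborhoods rather than the least credible edges.
A configuration flag (`edge_rule = "below"`) supports the opposite
direction for sensitivity analysis.

### Markov clustering

MCL simulates a random walk on the graph and alternates two operators on a
column-stochastic matrix: **expansion** (matrix power, default 2) spreads
probability along paths; **inflation** (entry-wise power, default 2.0,
followed by column renormalization) sharpens mass onto intra-cluster
routes. Iteration stops when successive iterates differ by less than 1e-8
in max-norm (or after 100 iterations, with a warning and a flagged result).
Entries below 1e-5 are zeroed after inflation to keep the matrix sparse; a
column's maximum entry is never pruned, so no column can empty. Self-loops
of weight 1 are added before normalization — canonical MCL practice that
damps the parity oscillation of bipartite-ish graphs. Inflation is the
resolution dial: larger values give more, smaller clusters; the default 2.0
is the standard choice of MCL implementations.

Clusters are read off the converged matrix: *attractors* are rows with
positive diagonal mass; each node joins the attractor carrying its column's
largest mass (ties to the smallest row index); attractor rows with
overlapping support are merged by connected components, guaranteeing a hard
partition — every protein in exactly one cluster. Cluster ids are ordered
by descending size, then by lexicographically smallest member, so output is
stable across runs. The matrix representation is sparse (`Matrix`)
throughout; dense and sparse arithmetic agree to well below the 1e-9
stochasticity tolerance asserted after every iteration.

### Pathway overrepresentation

Each cluster is tested against each pathway with an upper-tail
hypergeometric test: drawing the cluster's n in-universe genes without
replacement from a universe of N genes of which K belong to the pathway,
the p-value is P(X ≥ k) for the observed overlap k. Only pairs with k ≥ 1
are tested (a zero-overlap pair can never be called enriched; testing it
would only inflate the family), and Benjamini–Hochberg FDR is applied
across the whole family of tests. A pathway is significant in a cluster iff
q ≤ α (default 0.05). The universe defaults to the union of the GMT
members; a user-supplied universe (for example, all network proteins
mappable to genes) overrides it. All cluster members are tested — targets
and interactors alike — since module function is a property of the whole
module; protein-to-gene identifier mapping is supported via a two-column
table. The overlap report lists pathways significant in ≥ 2 and in ≥ 3
clusters; the latter is the headline signal of a shared program across
modules.

## The synthetic data

`generate_network()` draws a planted-partition (stochastic block model)
graph: 120 proteins in 6 equal communities, within-community edge
probability 0.6, between-community 0.02, 30 targets spread evenly across
communities. Integer scores are uniform on 150–999 with within-community
scores shifted up by 200 (clipped), which produces a weak, positive
score-versus-topology correlation — enough structure for the score filter
and correlation stages to act on without making the score a community
oracle. The block model is chosen because MCL's behavior on it is well
characterized and because elevated shared-neighbor statistics for true
edges versus non-edges arise naturally from community structure.

What the generator does **not** emulate: heavy-tailed (scale-free) degree
distributions, hub proteins, assortativity, or realistic identifier
vocabularies. Conclusions that ride on degree heterogeneity — for instance,
precisely how much better one link-prediction score is than another on a
real interactome — should not be extrapolated from these fixtures; passing
tests demonstrate correctness of the computations and recoverability of
planted structure, not field performance.

`generate_pathways()` adds 40 gene sets: background pathways sampled
uniformly (sizes 8–20), four *planted* pathways drawing 80% of their
members from one home community each, and one *shared* pathway spanning
three communities. The shared pathway is coextensive with its three home
communities. That choice is deliberate fixture design: the shared pathway
is the ground truth for cross-cluster overlap recovery, and a thinner plant
sits near the FDR detection boundary where recovery is a coin flip —
a failed recovery would then indict the fixture rather than the pipeline.
With an unambiguous plant, the end-to-end check is informative. With 20-node
communities a fractional plant is simply too small; real pathways, at
hundreds of genes, do not face this scale constraint.

All generators are pure functions of their specification (seed included)
and byte-reproducible.

## Determinism and problem sizes

One global pipeline seed feeds stage-derived seeds (a stable arithmetic
hash of the stage name), so the false-edge sample and the classifier folds
are independently reproducible and two runs with the same configuration
produce byte-identical outputs apart from the report timestamp.

The test suite validates the metric implementations against brute-force
oracles exhaustively on every non-isomorphic connected graph with up to 6
nodes (141 graphs) and on 100 seeded random graphs of up to 40 nodes; the
MCL implementation against an independent naive dense implementation on 50
seeded graphs; the hypergeometric tail against explicit combinatorial
summation on the full grid of valid configurations with universe size up to
25; and the end-to-end pipeline on the 120-node synthetic default. These
sizes keep the whole suite within a few minutes on one CPU while leaving no
untested code path; the statistical properties being checked (oracle
equality, partition recovery, FDR control) do not sharpen with larger
fixtures.

## Known limitations

* Identifiers are opaque strings; no mapping between database accessions
  and gene symbols is attempted beyond the optional user-supplied table.
* The false network is a topological contrast class, not a validated set of
  non-interactions; absence from a database is weak evidence of
  non-interaction.
* Welch tests on edge attributes treat edges as independent samples, which
  network data only approximates.
* Eigenvector centrality on a graph whose two largest components tie in
  dominant eigenvalue depends on the tie-break (largest component wins);
  the warning should be heeded when comparing such values across networks.
* MCL cluster counts depend on inflation; the default 2.0 is a convention,
  and module counts should be read qualitatively.
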