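---
title: "Methods: tripartite gene-chemical-disease interactome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tripartite gene-chemical-disease interactome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripnet)
```

# The model

`tripnet` analyses a *typed tripartite interaction network*: genes,
chemicals and diseases as nodes, and undirected annotated links of five
classes (gene-gene, gene-chemical, chemical-chemical, disease-gene,
disease-chemical; disease-disease links are not part of the model). Links
carry a set of curated interaction types — `therapeutic`,
`marker/mechanism`, `increases`, `decreases`, `affects` — plus optional
protein-modification tags (phosphorylation, ubiquitination, and ten
others). A link's *polarity* is `positive` when all its types are drawn
from {therapeutic, increases}, `negative` when all are drawn from
{marker/mechanism, decreases}, and `mixed` otherwise. Edges with no type
evidence at all (protein-protein interaction rows carry none) are
classified `mixed`: the positive/negative labels are claims about
evidence, and an empty type set supports neither claim.

Identity is a single case-sensitive namespace across kinds: the same name
may not denote both a gene and a chemical, and no synonym resolution is
attempted — inputs are expected to use database-normalized names.

# Network construction

Construction starts from four raw tables in the dialect of curated
toxicogenomics databases: chemical-gene rows (with a free-text interaction
description), chemical-disease and gene-disease rows (with a
`direct_evidence` field in {therapeutic, marker/mechanism, both, none}),
and a protein-protein interaction table.

**Disease-context filter.** An entity is *directly linked* when it has an
association row to a context disease. A chemical-gene row survives when at
least one endpoint is directly linked, so every retained gene or chemical
is within two steps of a context disease. PPI rows survive when both genes
are retained and at least one is directly disease-linked.

**Bidirectional deduplication.** Batch queries in both orientations emit
the same chemical-gene interaction twice; duplicates collapse to one
undirected edge whose type set is the union across orientations.

**The whole network** merges the filtered chemical-gene edges,
disease-association edges and PPI edges. It contains no chemical-chemical
links.

**The therapeutic network** retains only chemicals with at least one
therapeutic disease association (`therapeutic` or `both` — "both" asserts
a therapeutic indication and therefore qualifies), genes linked to a
retained chemical by a chemical-gene edge (a gene whose only anchor is a
disease association is dropped — the inclusion rule is about linkage to
therapeutic chemicals), all context diseases, and chemical-chemical edges
inferred from co-occurrence: when a second chemical's name appears
(word-boundary delimited, case-insensitive) in the free text of a
chemical-gene interaction, an edge between the two chemicals is created
with the types of the hosting interaction. Text matching is a stand-in
for pre-parsed interaction fields; it requires an explicit chemical
vocabulary and does no synonym handling.

# Jaccard similarity

For nodes $a, b$ with neighbour sets $N(a), N(b)$ — *including the node
itself when it has a self-interaction* —

$$J(a,b) = \frac{|N(a) \cap N(b)|}{|N(a)| + |N(b)| - |N(a) \cap N(b)|},$$

defined as 0 when both sets are empty. Including self-interactions
matters: two self-interacting genes that also interact with each other
can reach $J = 1$, whereas without self-loops two adjacent nodes always
differ in at least each other.

Linked-versus-unlinked comparisons split each pair class (DG, DC, CG) by
edge status and apply a one-sided Mann-Whitney U test (normal
approximation with tie and continuity correction; the coefficients are
massively tied at zero in sparse networks) of the alternative that linked
pairs are more similar.

**Percentile ranks within sub-networks** use the mid-rank convention
against all *other* pairs of the sub-network: the fraction of other
coefficients strictly smaller plus half the ties, times 100. Ranking
against the other pairs (rather than all pairs including the queried one)
makes a unique maximum rank exactly 100 while an all-tied sub-network
ranks everything 50. Bands follow a 25/75 split with boundaries assigned
downward: lower25 $[0,25]$, middle $(25,75]$, upper25 $(75,100]$.

# Perturbation stability

For a sub-network, every admissible missing edge (any unordered
non-adjacent pair that would not create a disease-disease link) is added
one at a time; the full Jaccard coefficient distribution over node pairs
is recomputed and compared to the unperturbed distribution with a
two-sided two-sample Kolmogorov-Smirnov test (exact below 25 pairs,
asymptotic otherwise — sub-network samples are small). Large mean
p-values mean the similarity measure is robust to small amounts of
missing curation; smaller sub-networks are more affected, which the test
suite asserts as a trend over nested sub-network sizes rather than
per-instance (single instances are noisy).

# Molecular-complex detection

The complex-detection procedure is reimplemented from its published
description. Vertex weighting: vertices of simple degree below the degree
cutoff (default 2) weigh 0; every other vertex weighs $k \times$ density
of the highest-$k$-core of its closed neighbourhood (self-loops ignored).
Complex growth: seeds are taken in decreasing weight (ties broken by node
id for determinism — the original is order-dependent and unspecified);
neighbours join breadth-first while their weight is at least
$w_{seed}(1 - \text{node score cutoff})$, each node joining at most one
complex, to a maximum depth of 100. Complexes lacking a 2-core are
dropped; the haircut removes degree-1 members. Scores are density
$\times$ size. Defaults (2, 0.2, 2, 100, haircut on, fluff off) are the
standard published settings; fluff is not implemented — it is off in
those defaults and its published description leaves the recruitment rule
for shared neighbours ambiguous.

Two behaviours of this algorithm matter for interpretation. First, the
20% recruitment window is narrower than the weight jump between adjacent
core orders ($k$ vs $k{+}1$ is a $1/(k{+}1)$ relative gap, e.g. 25% at
$k=3$), so in blocks that are dense but not complete the complex trims to
the densest core rather than the full block. Second, a single edge
between two dense regions whose weights lie within the seed's window
merges them into one complex. Both effects are visible in the
planted-recovery measurements of `scripts/acceptance.R`: recovery is
exact on complete, well-separated planted blocks (unit tests) but
partial, typically 0.6–0.8 mean node-set Jaccard, on Bernoulli(0.9)
blocks over a sparse background, where the matrix-clustering route
recovers the same blocks at about 0.9.

# Matrix clustering

The binary interaction matrix has one row/column per node (lexicographic
order), cell 1 where any interaction exists, and diagonal 1 only at
self-interacting genes. Row similarity is the *uncentered correlation*
$\sum x_i y_i / (\sqrt{\sum x_i^2} \sqrt{\sum y_i^2})$ — cosine on the
raw values, no mean-centring, the classic expression-clustering choice —
which on binary profiles measures shared interaction partners normalised
by profile sizes. All-zero rows have undefined similarity and are
excluded before clustering.

Agglomeration is average linkage (cluster-cluster similarity is the
unweighted mean of cross-pair similarities, maintained by the
Lance-Williams update), merging the most similar pair first, with exact
ties broken by the lexicographically smallest member id so runs are
deterministic. Because the published tool's tie-break is undocumented,
reproduced cluster counts on the deposited matrices are expected within a
small tolerance rather than exactly. The merge-height sequence is
cross-checked against `stats::hclust(method = "average")` in the test
suite; the agglomeration itself is implemented here because `hclust`
exposes neither the similarity semantics nor the tie-break.

A cut at threshold $t$ extracts maximal subtrees whose internal merges
all have similarity $\ge t$; subtrees have at least two leaves, so
singletons are never clusters. The clustered-node curve counts leaves in
clusters across a threshold grid (step 0.05 by default) and is monotone
non-increasing. Inflection detection smooths the curve with a 3-point
moving average (full windows only — shrunken end windows would fabricate
curvature at the boundary), takes the discrete second difference, and
reports each *curvature episode* (maximal run of constant nonzero sign)
at its central grid point, so a single knee in a piecewise-linear curve
is located at the knee itself.

# Link inference and validation

Unlinked pairs inside highly interconnected complexes are candidate novel
interactions; `candidate_pairs()` samples them uniformly (seeded) and
annotates each with its sub-network percentile band. An empty `evidence`
column is emitted for manual literature annotation — no text mining is
attempted.

`validate_against_reference()` evaluates the similarity signal against an
external gene-gene reference: validation pairs are reference edges whose
genes are both in the study network but whose interaction is absent;
self-interactions are excluded from validation set and background alike
(their similarity is trivially 1). The background is every unlinked
non-self gene-gene pair. The one-sided Mann-Whitney test asks whether
validation pairs are more similar than background; the decile histogram
bins mid-rank percentiles (computed against the background distribution)
with boundary values assigned to the lower bin, so the heavy zero-ties of
a sparse network visibly distort the background away from 10% per bin —
a property, not a bug, of tie-respecting percentiles.

# The synthetic-data generator

`generate_bundle()` emulates the statistical structure the analysis
assumes, at about a quarter of the published scale for desk-speed tests:
100 genes, 150 chemicals, 60 diseases. Background links are per-class
Bernoulli with defaults CG 0.012, GG 0.015, DG 0.015, DC 0.02, chosen so
that roughly 1.5% of node pairs are linked overall — the sparsity regime
of the real networks. Per-node multiplicative propensities are log-normal
with sd(log) 0.75, making degrees hub-dominated as in curated databases;
they are normalised to unit *mean* so the expected class density equals
the configured probability (unit median would inflate it by
$e^{\sigma^2/2}$).

Planted structure: three mixed-kind blocks of eight nodes, gene-dominant
(one chemical and one disease each) so that almost every within-block
pair belongs to an admissible class and the realised block density
tracks `planted_within_density` (default 0.9). Each block member is
anchored to a block disease so context filtering cannot dissolve the
block. 15% of planted gene-gene edges are withheld into a reference
network (plus 25% noise pairs); the default is deliberately modest
because withholding deletes exactly the edges that make blocks
recoverable — the dedicated validation study in `scripts/acceptance.R`
uses its own configuration (120 genes, six 14-node blocks, overlap 0.6)
sized to withhold at least 200 edges per draw. Chemical-gene rows carry
generated interaction text; 5% mention a second chemical to exercise
co-occurrence inference; 95% of rows are duplicated in the reverse query
orientation to exercise deduplication; 70% of chemical-disease rows carry
therapeutic evidence; 5% of genes get self-interactions.

What the generator does **not** emulate: real nomenclature and synonymy,
curation biases (the real tables correlate evidence types with entity
popularity), snapshot mixing between database versions, and
disease-disease comorbidity structure. Passing tests on bundles therefore
demonstrate algorithmic correctness and statistical behaviour under the
stated assumptions, not performance on real curated data.

# Numerical choices and problem sizes

* Exact string identity after whitespace trimming; kind collisions are
  load errors.
* Self-loops count once toward a node's neighbour count; the
  characteristic path length is the mean shortest-path length over the
  largest connected component (the published number is reported for a
  connected-in-practice network; the averaging convention is ours).
* Empty networks summarise to zero counts with NaN ratios.
* Mann-Whitney: always the normal approximation with tie correction —
  exact p-values are unavailable under ties anyway.
* The permutation calibration of the linked/unlinked test pools 500 label
  permutations over five independent bundle draws: a single draw's
  rejection rate varies with its tie structure beyond permutation-level
  binomial error.
* Test-suite and acceptance problem sizes: bundles of ~310 nodes
  (default), ~210 nodes (validation study), sub-networks of 15–22 nodes
  for stability, oracle comparisons at 10 nodes or fewer under
  exhaustive enumeration. The full suite runs in well under a minute;
  the acceptance script in under a minute.

# Known limitations

* Cluster counts at fixed thresholds depend on tie-breaking in the
  agglomeration; only counts, not exact memberships, should be compared
  across implementations.
* The complex-detection recruitment window interacts with core-order
  granularity (see above); planted-block recovery through that route is
  partial at within-block density 0.9 and should be read alongside the
  matrix-clustering route.
* Co-occurrence inference is purely lexical; it cannot find co-occurrence
  expressed through synonyms or abbreviations.
* The pipeline holds all-pairs similarity tables in memory; it is
  comfortable to a few thousand nodes but not designed beyond that.
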