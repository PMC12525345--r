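---
title: "Scoring DEG clusters by embedding proximity to a causal gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring DEG clusters by embedding proximity to a causal gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`degnet` integrates per-dataset differential expression with a
confidence-scored protein–protein interaction (PPI) network and asks, for
each disease dataset, which groups of differentially expressed genes
(DEGs) are topologically close to the disease-causal gene. This vignette
is the package's account of the underlying model, the tunable parameters,
the synthetic benchmark and the numerical choices a maintainer should
know about.

## The model

The quantity of interest is the *proximity* of a gene set to a designated
causal gene in a gene-level interactome. Direct graph distances are poor
proxies for functional closeness in PPI networks: two genes can share an
interaction neighbourhood without being adjacent. The package therefore
works in an embedded space:

1. The filtered interactome (edges with confidence strictly above 150,
   components of at least 5 nodes) is binarized and symmetrically
   degree-normalized, `N = D^(-1/2) A D^(-1/2)`.
2. node2vec-style random walks (10 walks of length 100 per node,
   transition weights proportional to the entries of `N`; with
   return/in-out parameters p = q = 1 the walk is first-order) feed a
   skip-gram model with negative sampling (window 10, 128 dimensions),
   yielding one vector per gene.
3. Pairwise cosine similarity is calibrated into a *link probability* by
   logistic regression of the edge indicator on similarity, trained on
   all edges against an equal-size uniform sample of non-edges. This
   turns an uncalibrated geometric quantity into "the probability these
   two genes would be connected".
4. For a causal gene `c`, every other gene gets
   `P(g ~ c) = logistic(b0 + b1 * S(g, c))`, which is rank-normalized
   over all network genes to `rank_score` in (0, 1] (mean ranks under
   ties, so the distribution is uniform on {1/n, ..., 1} absent ties).
5. A cluster's members contribute p-like values `1 - rank_score`,
   combined by Fisher's method (`X = -2 * sum(log p)` against a
   chi-square with 2k degrees of freedom); the reported score is
   `1 - combined_p`. Under the null (members exchangeable with random
   genes) the per-gene values are approximately uniform, so scores are
   approximately uniform on (0, 1); a cluster whose members all rank
   near the top scores close to 1.

The estimator is exposed as a fitting function, `fit_proximity()`,
returning a `proximity_model` with `print`, `summary`, `coef` and
`predict` methods; `predict(model, causal)` yields the per-gene table
that `score_clusters()` and `rank_isolated()` consume.

### Assumptions

- The interactome is undirected and simple; confidence scores are used
  only for filtering, not as walk weights (binarization before
  normalization). Edge evidence strength is kept in the provenance
  output but treating it as a transition weight would conflate evidence
  quantity with topology.
- Proximity is meaningful because the network has community structure
  around the causal gene; on an Erdős–Rényi graph the scores are
  calibrated but uninformative by construction.
- Fisher's combination treats member ranks as independent; genes in one
  cluster are positively dependent, so combined p-values are
  anti-conservative in absolute terms. Scores should be read as a
  ranking device across clusters, not as frequentist p-values.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `network.score_min` | 150 | strict lower bound on edge confidence (0–1000 scale) |
| `network.min_component_size` | 5 | smallest connected component retained |
| `network.min_cluster_size` | 3 | smallest Louvain community kept as a cluster |
| `cpm_threshold` | 2 | CPM level a library must reach |
| `min_libraries` | 2 | libraries per group at that level (small groups) |
| `padj_threshold` | 0.05 | BH-adjusted significance for DEG calls |
| `log2fc_cutoff` | per dataset | absolute log2 fold-change cutoff |
| embedding (scoring) | 128 / 100 / 10 / 1 / 1 / 10 | dimensions, walk length, walks per node, p, q, window |
| embedding (visualization) | 64 / 30 / 200 / 1 / 1 / 10 | second parameter set feeding the 2-D layout |
| UMAP | n_neighbors 15, min_dist 0.1 | layout of the visualization embedding |
| `scoring.epsilon` | 1e-12 | floor on per-gene p-values before logs |
| `probability_mode` | `"rank"` | cluster-score conversion (see below) |

Design choices that were genuinely open, and how they were settled:

- **"Above 150" is strict** (`> 150`): the plain reading of "above"; the
  boundary case is tested explicitly.
- **Degree normalization is symmetric** (`D^(-1/2) A D^(-1/2)`) rather
  than row-stochastic: it keeps the matrix symmetric, so downstream
  cosine similarity treats both endpoints identically. The
  row-stochastic form is available via
  `normalized_adjacency(net, mode = "row")`.
- **Clustering runs on the DEG-induced subgraph**, not the whole
  network: this is what makes "isolated DEGs" a meaningful category and
  matches the cluster-size regime the method is designed for. The causal
  gene is never injected into the induced subgraph; it enters only
  through proximity scoring.
- **Louvain communities are split into connected parts** before size
  filtering — a repair rule, since a modularity community that is
  internally disconnected has no useful interpretation as a module.
  Cluster ids are assigned by decreasing size, then lexicographic first
  member, so runs are reproducible.
- **Fisher combines p-values, but the model produces probabilities.**
  The default (`probability_mode = "rank"`) converts each member's
  association probability to an upper-tail rank p = 1 − rank_score
  before combining; this makes strong association mean small p and puts
  the best attainable cluster score at 1.00. The direct conversion
  (p = 1 − association probability) is one flag away
  (`probability_mode = "direct"`); it is sensitive to the link model's
  calibration plateau and is kept only as a diagnostic.
- **Rank normalization is taken over all network genes**, not only the
  dataset's DEGs: the reference distribution should not depend on how
  many genes happened to pass the DEG cutoffs.
- **Negative sampling** for the link model is uniform over non-adjacent
  pairs at ratio 1:1, the simplest scheme that is reproducible under a
  seed; the positive set can be capped for very dense networks.
- **uDEG triage** adds an explicit `other` category beyond
  coding/ncRNA/pseudogene, so the three named categories are not forced
  to sum to the uDEG total when a biotype is missing or unusual.
- **Enrichment universes**: cluster over-representation uses the
  dataset's network-mapped expressed genes (the space clusters were
  formed in) with BH-adjusted p < 0.05; the cross-dataset comparative
  term network uses unadjusted p < 0.05 per dataset. Both thresholds are
  configuration keys. Ancestor pruning in the comparative network
  applies along the full transitive closure of the hierarchy, not just
  direct parents.
- **Percentage reporting** rounds half up at one decimal. One published
  reference figure for the share of down-regulated DEGs (63.6%) is only
  reproduced under truncation — 100·349/548 = 63.686 rounds to 63.7 —
  so the package reports 63.7 and the test tolerates the 0.1 gap.

## Numerical choices

- The embedding trainer is single-threaded C++ with an internal xorshift
  RNG, so a seed fully determines walks, training order and negative
  draws; R-side stages (Louvain order, sampling) draw from R's RNG via
  per-stage seeds derived from the single global seed
  (`derive_seed(global, stage)`), letting one stage be rerun without
  perturbing the others.
- Per-gene p-values are floored at 1e-12 before logs; without the floor
  a top-ranked gene (rank_score = 1) would contribute log(0).
- Rank ties use mean ranks, which keeps the rank distribution unbiased
  under duplicated probabilities.
- If the link-model fit encounters (near-)separation — e.g. on a
  network of disconnected cliques where similarity separates edges
  perfectly — predicted probabilities are clipped to
  [1e-6, 1 − 1e-6] and a warning is raised; a constant similarity
  matrix short-circuits to a flat model at the base rate.
- The 2-D view is a compact in-package UMAP (exact k-nearest-neighbour
  fuzzy graph with smooth-knn bandwidths, kernel parameters fitted from
  `min_dist`, SGD layout with PCA initialization), written because no R
  UMAP implementation is available to the package; it targets small
  networks (dense distance matrix) and is deterministic under a seed.
  Networks smaller than `n_neighbors` shrink the neighbourhood with a
  warning.
- Zero-degree nodes are rejected by `normalized_adjacency()`; by
  construction they cannot occur after component filtering with a
  minimum size of 5.

## The synthetic benchmark

`simulation_config()` defines the package's reference conditions: a
stochastic block model with 500 genes in 5 equal blocks, within-block
edge probability 0.2 and between-block 0.01, integer confidence scores
uniform in (150, 1000] plus a 10% fraction of decoy edges scored at or
below 150, one causal gene inside the causal block, 10 DEGs planted in
the causal block and 10 in the most distant block (|log2FC| ~
Normal(2, 0.3), adjusted p ~ Uniform(0, 0.01)), 20 extra unmapped DEGs
with biotypes at 80% coding / 15% ncRNA / 5% pseudogene, and
negative-binomial counts (dispersion 0.2, 3 libraries per group) whose
treatment means shift by 2^log2FC. The SBM was chosen over
configuration-model rewiring because the proximity logic presupposes
community structure around the causal gene; the DEG effect sizes leave a
wide margin over the 0.6 classification cutoff so recovery tests are
about the network method, not borderline calling. Adjusted p-values are
simulated directly because differential-expression model fitting is out
of the package's scope (statistics tables are consumed, not computed).

What the generator emulates: a modular interactome with decoy
low-confidence edges, DEG sets with known distance to the causal gene,
silent genes exercising the expression filter, and a term catalog whose
block terms align with the planted structure (plus pair-union parent
terms and random decoy terms for the pruning and specificity tests).
What it does not emulate: realistic RNA-seq read-level noise, hub-like
degree heterogeneity of real PPI networks, correlated annotation terms,
or batch structure. Passing the recovery tests therefore shows the
machinery is correct and well calibrated, not that any particular real
dataset would yield the same cluster ranking.

## Problem sizes used by the test suite

Unit tests run on graphs of 5–200 nodes with reduced embedding settings
(32–64 dimensions, shorter walks). The end-to-end checks use the
reference 500-gene benchmark: planted-signal recovery across 20 seeds
(the near cluster must beat the far cluster in at least 18), null
calibration over 200 causal-gene/cluster draws on 150-node random graphs
(mean score within [0.40, 0.60]), and byte-identical score tables across
two same-seed pipeline runs. `scripts/acceptance.R` recomputes the
headline quantities at the same sizes.

## Known limitations

- Only first-order walks (p = q = 1) are implemented; the biased
  second-order walk is rejected at configuration time.
- Scores compare clusters within one network and causal gene; they are
  not calibrated across networks of different size or density.
- The comparative term network treats term namespaces as opaque catalog
  metadata and does not parse ontologies (no OBO support); hierarchies
  come from a plain parent/child table.
- Multi-seed (multi-causal-gene) scoring is out of scope; each dataset
  has exactly one causal gene.
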