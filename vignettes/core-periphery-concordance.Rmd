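---
title: "Measuring core-periphery community concordance in weighted gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring core-periphery community concordance in weighted gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreperiphery)
```

## The model and its assumptions

The package asks a single quantitative question in several guises: do the
candidate core genes of a complex disorder occupy a privileged position in a
tissue's weighted gene functional network? "Privileged" is operationalized
two ways.

**Centrality.** Node strength $s_i = \sum_j w_{ij}$ summarizes how strongly
a gene is functionally tied into the tissue. We compare core against
peripheral strengths with a two-sided Mann–Whitney U test and require the
core median to exceed the peripheral median before declaring the core set
central. The test assumes exchangeability under the null and nothing about
the strength distribution's shape — appropriate because strengths in
functional networks are heavy-tailed.

**Community concordance.** Communities are detected by Louvain modularity
maximization ($Q$ at resolution 1, weighted) on the full network and,
separately, on the core subgraph (only edges joining two core genes). The
two partitions are intersected into a contingency table whose cell
$n_{ij}$ counts genes in core cluster $i$ and full cluster $j$, and
association is measured by

$$X^2 = \sum_{ij} \frac{(n_{ij} - n_{i\cdot} n_{\cdot j}/n)^2}{n_{i\cdot} n_{\cdot j}/n},
\qquad V = \sqrt{\frac{X^2/n}{\min(k-1,\,r-1)}}.$$

Cramér's V is used (rather than raw $X^2$, NMI or ARI) because it
normalizes across tables of different shapes, which is what cross-tissue
comparison needs: different tissues yield different numbers of core and
full clusters. $V$ is a descriptive concordance measure here, not a test
statistic — its sampling behavior is benchmarked empirically (below)
instead of asymptotically.

The implicit assumptions are worth stating: the edge weights are
comparable within a network (they are posterior-probability-like scores in
$(0,1]$); the community structure at Louvain's final level is the relevant
mesoscale; and the core gene list, however noisy, is enriched for genes
with direct effects.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `alpha` (centrality, phenotype) | 0.05 | probability | conventional two-sided level |
| `min_size` (community filter) | 10 full / 1 core | genes | full networks produce a few tiny residual communities that would add near-empty contingency rows; core subgraphs are small enough to keep whole |
| `n_restarts` (Louvain) | 10 | runs | the local-move phase is order-dependent; best-of-restarts makes results reproducible and slightly better |
| `p_cut`, `q_cut` (enrichment) | 0.001, 0.05 | probability | the conventional defaults of two-list hypergeometric enrichment tools |
| `n_replicates` (sampling / regrouping controls) | 10 | replicates | enough for a t-based 95% CI on the mean V while staying cheap |
| `mu_w` (benchmark) | 0.2 | weight fraction | moderate mixing: communities are recoverable but not trivial |

Thresholds enter only through the declared cut-offs; no statistic is
silently recomputed at another level.

## Numerical and procedural choices

* **Edge ingestion.** Duplicate undirected pairs keep the *maximum* weight
  (a "top edge" is the strongest reported association); self-loops are
  dropped; weights must lie in $(0,1]$, with an opt-in clamp for weights
  slightly above 1 and a hard error for non-positive weights, which cannot
  be clamped meaningfully.
* **Mann–Whitney.** Exact enumeration when both groups have at most 20
  untied values, otherwise the tie-corrected normal approximation without
  continuity correction. All-tied inputs are an error, not a p-value.
* **Louvain.** Delegated to igraph's implementation, driven by explicit
  seeds; restarts use consecutive seeds and ties in $Q$ keep the first
  restart. Community ids are re-indexed 1..K by descending size so labels
  are stable. Louvain is a greedy heuristic: on small graphs with genuine
  modular structure it attains the exhaustive-search optimum (this is
  tested over all set partitions of 6-node graphs), but on near-degenerate
  graphs with almost-uniform weights it can converge to a local optimum
  that no number of restarts escapes. That is a property of the algorithm
  family, accepted deliberately; the analysis targets networks with real
  community structure.
* **Contingency tables.** Unassigned (filtered) genes are excluded with a
  message; empty rows/columns are dropped with a warning before $X^2$ and
  $V$ because the expected-count formula is undefined at zero marginals;
  $k$ and $r$ refer to the post-drop table. Column reordering for display
  uses an exhaustive maximum-diagonal assignment up to 8 columns (a greedy
  fallback above), and never changes the counts.
* **Sampling control.** Nodes are drawn *without* replacement with
  probability proportional to strength via sequential renormalized draws —
  a with-replacement scheme could not return a fixed-size node set.
  Edgeless replicates are resampled up to 5 times, logged.
* **Degenerate inputs.** Edgeless networks cannot be clustered (error);
  an edgeless core subgraph is an error; Cramér's V on tables with fewer
  than 2 surviving rows or columns is an error (association undefined);
  Welch comparisons need two subjects per group and nonzero variance
  somewhere.
* **Floating point.** $V$ is clamped to $[0,1]$ against representation
  error; q-values use the standard step-up and are verified against a
  brute-force implementation.

## What the synthetic generators emulate — and what they do not

The **LFR-style benchmark** (`generate_lfr()`) reproduces the features the
calibration depends on: truncated power-law degrees (exponent 2, mean
solved numerically from the truncation points), truncated power-law
community sizes, a per-node internal/external stub split targeting the
weighted mixing fraction, configuration-model pairing with rejection of
self- and duplicate pairs, and uniform weights on $(0.4, 1)$ so the
external *weight* fraction matches the external *degree* fraction in
expectation. It does not replicate the reference C++ generator's
micro-behavior (exact degree sequences, weight-strength coupling via a
separate exponent); only the distributional properties the concordance
claims rest on are reproduced, and the tests assert those properties
directly (mean degree within 10%, realized mixing within ±0.05,
bit-identical outputs under a fixed seed).

The calibration experiment selects either the top-strength nodes or a
uniform random sample. "Nodes with average strength distribution" is
implemented as uniform sampling because a uniform sample reproduces the
full strength distribution in expectation; this was a genuinely open
design point and the uniform reading is the simplest one consistent with
the observed overlap of the sampled and full distributions.

The **tissue simulator** (`generate_tissue()`) operationalizes the
relevant/irrelevant contrast as a single `concordance` dial: aligned core
genes sit in per-community high-strength hub strata with up-weighted
core–core edges; scattered core genes are placed uniformly with sparse
weak core–core edges. It is a block model, not a GIANT-like integrated
network: it has no overlapping functional contexts, no heavy-tailed
weights, and its communities are equal-sized. Passing tests on it
demonstrate that the pipeline *detects planted structure and orders
regimes correctly* — not that any particular real tissue attains a
particular V.

The **annotation simulator** plants signal terms drawn ≥ 70–80% from one
home cluster amid uniform noise terms; the **phenotype simulator** gives
each subject a Poisson number of uniformly drawn variant genes and adds
per-subcluster trait shifts plus Gaussian noise (IQ sd 15 points, walking
sd 2 months around baselines of 100 points and 13 months — conventional
population-scale values). Real variant data are neither uniform across
genes nor independent across subjects; the simulators exist to verify
parameter recovery (planted shifts recovered within 2 standard errors at
3000 subjects) and null behavior (no effect where none is planted).

## Problem sizes

The test suite and the acceptance script run the benchmark calibration at
1/10 scale — 2500 nodes, mean degree 30, maximum degree 300, community
sizes 400–800, selecting the 75 strongest nodes — which preserves the
within-community hub connectivity that drives the result while keeping a
single run around a second. Unit tests use 300–800-node networks and
600-node tissue simulations; phenotype recovery uses 3000 subjects. The
full-scale benchmark (25,000 nodes, mean degree 300, 745 selected nodes)
runs through the identical code path via `lfr_params()` when wanted.

## Known limitations

* Louvain non-determinism is handled by best-of-restarts; a consensus
  clustering across runs would be more thorough and is not implemented.
* Only the final Louvain level is reported; no hierarchical or overlapping
  communities.
* The enrichment stage treats annotation terms as flat sets (no ontology
  graph propagation) and implements only the fixed target-vs-background
  mode, mirroring the two-list hypergeometric design it follows.
* The phenotype stage performs no covariate adjustment; carriers are
  compared to all remaining subjects with Welch tests and per-trait BH
  correction, with the correction family size configurable because tested
  subclusters may be dropped for lack of carriers.
* Cramér's V on small, sparse subgraphs (many singleton clusters) is
  biased upward relative to its large-sample behavior; the sampling and
  benchmark controls are computed at matched sizes precisely so that
  comparisons are like-for-like.
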