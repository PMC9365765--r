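# coreperiphery

Quantifying how strongly candidate disease "core" genes cluster within
tissue-specific weighted gene functional networks.

Under the omnigenic view of complex disorders, a limited set of core genes
affects a trait directly while the remaining ("peripheral") genes expressed
in a relevant tissue act indirectly, through the gene interaction network.
That picture makes a testable network prediction: in a disorder-relevant
tissue, the candidate core genes should (i) be unusually *central* —
carrying high node strength — and (ii) form communities that line up with
the communities of the full network, because peripheral interactions
reinforce rather than scramble them. `coreperiphery` implements the full
analysis for anyone with an edge-list network and a candidate gene table:
geneticists studying neurodevelopmental disorders, and network biologists
who want a calibrated community-concordance statistic.

## The statistics at the core

* **Node strength** `s_i = Σ_j w_ij`: the weighted generalization of degree.
  Core-gene centrality per tissue is tested with a two-sided Mann–Whitney U
  test of core vs peripheral strengths (exact for small groups), and a gene
  set only counts as "central" when it is also higher in median. Tissues are
  then cross-tabulated against brain/non-brain labels with an enrichment
  factor and an uncorrected 2×2 chi-squared.
* **Modularity** `Q = (1/2m) Σ_ij [w_ij − s_i s_j / 2m] δ(c_i, c_j)`,
  maximized by seeded Louvain community detection with best-of-restarts.
* **Core–periphery concordance.** Cluster the full network and the core
  subgraph (only edges joining two core genes), intersect the two
  partitions into a contingency table `n_ij`, and compute

  `X² = Σ_ij (n_ij − n_i·n_·j/n)² / (n_i·n_·j/n)`,
  `V = sqrt((X²/n) / min(k−1, r−1))`.

  Cramér's V ∈ [0, 1] is comparable across tables of different shapes:
  V = 1 means every core cluster is embedded in one full cluster, V = 0
  means core genes scatter independently of the full communities.
* **Controls.** Strength-weighted graph sampling (core-sized subgraphs drawn
  with probability ∝ strength, 10 replicates) benchmarks what V a "typical"
  central subgraph achieves; an LFR-style planted-community benchmark shows
  that top-strength subgraphs reach V = 1 while distribution-matched random
  subgraphs do not; a label-permutation regrouping control shows annotation
  enrichment collapses when clusters are randomized.
* **Downstream interpretation.** Hypergeometric target-vs-background
  enrichment with fold `(b/n)/(B/N)` and Benjamini–Hochberg q-values, and
  Welch t comparisons of subject phenotypes between carriers of disruptive
  variants in a subcluster and everyone else.

All inputs are plain text (3-column edge lists, GMT annotation sets,
delimited phenotype tables), and every synthetic generator (LFR benchmark,
tissue simulator with tunable core concordance, annotation and phenotype
simulators) uses explicit seeds, so the entire pipeline runs end to end
with no external data.

## Worked example

Simulate a fully concordant ("relevant-tissue") network, test core
centrality, and measure the core–periphery concordance:

```r
library(coreperiphery)

sim <- generate_tissue(n_nodes = 800, n_communities = 4, core_size = 80,
                       concordance = 1, seed = 42)

centrality_test(node_strength(sim$network), sim$core, tissue = "relevant")
#> # A tibble: 1 × 8
#>   tissue   n_core n_peripheral u_statistic  p_value core_median peripheral_median core_central
#>   <chr>     <int>        <int>       <dbl>    <dbl>       <dbl>             <dbl> <lgl>
#> 1 relevant     80          720       57388 3.78e-48        26.9              12.1 TRUE

full      <- louvain_communities(sim$network, seed = 42)
core_part <- louvain_communities(core_subgraph(sim$network, sim$core), seed = 42)
tab <- reorder_diagonal(cluster_contingency(core_part, full))
tab
#> Core/full cluster contingency table (4 x 4, n = 80)
#>     FC1 FC2 FC3 FC4
#> CC1  20   0   0   0
#> CC2   0  20   0   0
#> CC3   0   0  20   0
#> CC4   0   0   0  20
glance(tab)
#> # A tibble: 1 × 6
#>    chi2     v df_norm     n     k     r
#>   <dbl> <dbl>   <dbl> <int> <int> <int>
#> 1   240     1       3    80     4     4
```

The core genes are strongly central (U = 57388, p ≈ 4e−48, higher median),
and each of the 4 core clusters falls entirely inside one full-network
community, so V = 1 — the perfectly concordant regime. The
strength-weighted sampling control shows that even generic central
subgraphs of this network sit slightly below that:

```r
sample_control(sim$network, size = 80, full_partition = full,
               n_replicates = 10, seed = 42)
#> Graph-sampling control: 10 replicates, mean V = 0.961 (sd 0.017, 95% CI [0.948, 0.973])
```

Lowering `concordance` in the generator scatters the core genes and V drops
accordingly. The whole multi-tissue study (strengths → clustering →
concordance → controls → enrichment → phenotypes) runs from one declarative
config via `run_study()`; see `?run_study`.

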