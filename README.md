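# covnet

Group-level **anatomical covariance network** analysis of regional
gray-matter volumes, for researchers comparing structural brain organization
between groups — e.g. patients before and after surgery against healthy
controls — when each group contributes one network rather than one network
per subject.

## What it computes

Given per-group tables of subjects × regions volumes (such as the 90-region
AAL parcellation), covnet:

1. builds each group's association matrix `R` of Pearson correlations of
   regional volumes across subjects (structural covariance);
2. binarizes `R` across a density grid `d = 0.10, 0.12, …, 0.50`, keeping the
   `k = round(d·R(R−1)/2)` strongest edges at each density;
3. computes, per density, the global metrics — clustering coefficient `C`,
   characteristic path length `L`, global efficiency `E_glob`, local
   efficiency `E_loc`, small-worldness `σ = (C/C_rand)/(L/L_rand)` against 20
   degree-preserving null networks, modularity `Q` — and the nodal metrics
   (betweenness centrality, degree, clustering);
4. identifies BC hubs (`BC > mean + 1·SD` and `+ 2·SD`) and quantifies
   resilience to targeted attack (removal by decreasing BC) and random
   failure (random removal, averaged over repetitions) via the relative size
   of the largest connected component;
5. compares groups by one-tailed permutation tests (1000 repetitions) on the
   area under each metric's density curve, with
   `p = (#{null ≥ obs} + 1)/(n_perm + 1)`, plus Benjamini–Hochberg
   FDR-corrected regional comparisons of the nodal metrics;
6. reproduces the standard clinical outcome statistics (one-way ANOVA,
   Pearson χ², paired *t*, outcome percentages).

A seeded synthetic-data generator (`covariance_spec()`,
`planted_hub_adjacency()`, `clinical_spec()`) plants known covariance
structure so every stage can be validated end to end.

## Worked example

```r
library(covnet)

regions <- aal_region_names(90)
A <- planted_hub_adjacency(90, hub_nodes = c(5, 17), hub_degree = 8,
                           background_p = 0.06, seed = 1)
pre  <- generate_group_volumes(covariance_spec(90, A, edge_weight = 0.25,
                                               seed = 11), 21, regions, "pre")
ctl  <- generate_group_volumes(covariance_spec(90, A, edge_weight = 0.25,
                                               seed = 13), 32, regions, "control")

assoc <- compute_association_matrix(pre)
min_connected_density(assoc)
#> [1] 0.05243446

net <- binarize_at_density(assoc, 0.3)
net
#> <binary_network> 90 regions, 1202 edges (density 0.300)
clustering_coefficient(net)$mean
#> [1] 0.418793
global_efficiency(net)
#> [1] 0.6490221
set.seed(1); small_worldness(net)$sigma
#> [1] 1.368858

nod <- betweenness_and_degree(net)
identify_hubs(nod, 2)
#> <hub_set> BC > mean + 2 SD (mean 31.42, SD 9.81): roi_25_R, roi_28_L, roi_44_R
targeted_attack(net)$auc
#> [1] 0.4933333

builder <- function(t) resilience_auc_over_grid(
  suppressWarnings(build_networks(compute_association_matrix(t))),
  "random", n_repetitions = 20, seed = 2)
auc_permutation_test(builder, pre, ctl, n_perm = 1000, tail = "upper",
                     seed = 3)  # takes a minute or two
#> <permutation_result> pre vs control: diff 0.0001, one-tailed (upper) p = 0.05495 (n_perm = 1000)
```

The network is connected everywhere on the default density grid
(`min_connected_density` ≈ 0.052 < 0.10), its topology is mildly small-world
(σ ≈ 1.4), and its targeted-attack AUC sits near the complete-graph value of
0.5, i.e. the synthetic network is robust. Both groups share the same
generative structure, so the resilience contrast does not reach
significance — the p-value is the quantity a study would report.

`run_full_analysis()` chains all of the above for two or more groups and
writes association matrices, per-density networks, metric curves with AUCs,
hub tables, resilience curves, all pairwise contrasts and regional
comparisons, a `report.json` and a `manifest.csv` into an output directory;
reruns with the same `run_config()` are byte-identical.

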