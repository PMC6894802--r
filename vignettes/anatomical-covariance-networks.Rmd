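---
title: "Anatomical covariance networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical covariance networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covnet)
```

## The model

covnet analyzes *structural covariance* networks: given a group of subjects
with regional gray-matter volumes over a fixed parcellation (typically the 90
cortical and subcortical regions of the AAL atlas), the group's network is the
region-by-region matrix of Pearson correlations of volumes across subjects.
One network per group — not per subject — so group comparison cannot rely on
subject-level variance and instead uses permutation of subjects between
groups.

The association matrix is binarized by *density thresholding*: at density
$d$, the $k = \mathrm{round}(d \cdot R(R-1)/2)$ strongest edges are kept and
given weight 1. Because a single threshold is arbitrary, every metric is
computed across a grid of densities and summarized by its trapezoidal area
under the curve (AUC); all inference operates on AUCs. The default grid is
$d = 0.10, 0.12, \dots, 0.50$ (21 densities), the conventional range for
group anatomical covariance studies: below it networks fragment, above it
weak (likely spurious) correlations dominate.

On each binary network the package computes:

* **C** — mean Watts–Strogatz clustering (nodes with degree < 2 contribute 0);
* **L** — characteristic path length over mutually reachable pairs;
* **E~glob~** — mean inverse shortest-path length ($1/\infty = 0$);
* **E~loc~** — mean over nodes of the global efficiency of each
  neighborhood subgraph;
* **σ** — small-worldness $(C/C_{rand})/(L/L_{rand})$ against degree-preserving
  null networks;
* **Q** — Newman modularity of a multilevel greedy partition;
* per node: betweenness centrality (BC, Brandes counting, unnormalized),
  degree, and clustering.

Hubs are regions whose BC exceeds the across-region mean by more than 1 or 2
sample standard deviations. Resilience is assessed by sequential node
removal — targeted attack removes in decreasing order of intact-network BC;
random failure removes in random order, averaged over repetitions — tracking
the size of the largest connected component relative to the original node
count.

## Statistical inference

Between-group differences in any AUC (global metrics and resilience) are
tested with a one-tailed nonparametric permutation test, 1000 repetitions by
default. Each draw reassigns subjects between the two groups (label shuffling
preserving group sizes; or, for before/after contrasts on the same subjects,
independent pre/post swaps with probability ½), recomputes both networks from
scratch, and records the AUC difference. The p-value is the percentile
position of the observed difference with the add-one correction
$p = (\#\{\text{null} \ge \text{obs}\} + 1)/(n_{perm} + 1)$, so $p \in (0,1]$
and never exactly 0. Draws producing a non-finite statistic (e.g. an
undefined σ on a degenerate null) are discarded and counted.

Regional comparisons test, per region, the AUC over densities of a nodal
metric (BC, degree or clustering), then apply Benjamini–Hochberg FDR at 0.05
across the regions. The permutation draws are shared across regions within a
test, the standard construction.

Clinical outcome statistics use the classical tools: one-way ANOVA for age,
Pearson χ² (no continuity correction) for sex and categorized seizure
frequency, two-sided paired *t* for drug counts and IQ/DQ, and outcome
category percentages rounded half-up to one decimal. Because the literature
is ambiguous about whether seizure reduction is tested as a χ² on a
categorized table or a paired comparison on counts, `clinical_summary()`
computes both, clearly labelled.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `d_min`, `d_max`, `step` | 0.10, 0.50, 0.02 | density grid (21 points) |
| `n_perm` | 1000 | permutation repetitions per contrast |
| `n_random` | 20 | null networks per density for σ |
| `n_failure_repetitions` | 20 | random removal orders per density |
| `mode` | `"signed"` | edge ranking by raw r (vs `"absolute"`) |
| `fdr` | 0.05 | BH level for regional comparisons |

Signed ranking is the default because anatomical covariance studies in the
GAT lineage threshold positive covariance; absolute-value ranking is a switch
away for sensitivity analyses. The paired flag and the tail direction are
declared per contrast — the package does not guess directionality.

The number of random-failure repetitions is not standardized in the
literature; 20 mirrors the size of the σ null ensemble and makes the
per-density mean curve stable to within a few percent on 90-node networks.

## Numerical and design choices

* **Edge count rounding** is round-half-to-even (base R `round`), so the
  90-region grid keeps 400 edges at density 0.10 ($400.5 \to 400$). Ties in
  correlation are broken by lexicographic region-pair order; results are
  platform-deterministic.
* **Disconnected networks.** L excludes unreachable pairs from its mean and
  reports their count; E~glob~ handles disconnection natively. The default
  grid sits at or above full connectivity for realistic inputs, so this is an
  edge-case policy, not a routine correction. `min_connected_density()`
  reports the connectivity threshold for validation.
* **σ null model.** Degree-preserving rewiring is the field default (an
  Erdős–Rényi G(n,m) null is available behind a flag). Nulls are sampled
  along a single Maslov–Sneppen chain per density: a burn-in of 10·|E| swap
  attempts from the observed network, then one sample every further 2·|E|
  attempts until 20 nulls are collected. The chain targets the uniform
  distribution over graphs with the given degree sequence; consecutive
  samples are mildly correlated, which is immaterial here because only the
  ensemble *mean* of C and L enters σ, and it cuts the cost of
  permutation-testing σ by roughly a factor of four.
* **Modularity optimizer.** A deterministic multilevel greedy (Louvain-type)
  optimizer with sequential node sweeps and first-best tie-breaking. Q is
  compared between groups only as an AUC, so what matters is that the
  optimizer is fixed, deterministic and competitive; tests verify its Q
  matches igraph's scoring of the same partition exactly and its optimized Q
  is within noise of igraph's own multilevel result.
* **Targeted attack** uses the static ranking (BC computed once on the intact
  network), the convention of the graph-analysis toolboxes this package
  follows; a recompute-after-each-removal variant is available via
  `targeted_attack(recompute = TRUE)`.
* **Resilience curves** run from zero removals (relative largest component 1
  for a connected network) to complete removal (0 at fraction 1), and their
  AUC is the trapezoid over the removal fraction. With this convention a
  complete graph has AUC exactly ½ in both attack modes, a convenient
  closed-form anchor used by the tests. Note that "more edges ⇒ higher
  targeted-attack AUC" is *not* a theorem: a cycle attacked under tie-broken
  equal BC degrades as slowly as a complete graph, and adding a chord can
  concentrate BC into a genuinely more damaging removal order. The
  monotonicity intuition holds on star- and short-path-like fixtures, and
  that is where the test suite asserts it.
* **Hub thresholds** use the sample (n−1) SD. Hub tables are emitted per
  density; the default report also summarizes at the grid midpoint, since a
  single representative density is what hub tables conventionally print.
* **Seeds.** Every stochastic stage (σ nulls, random failure, permutation)
  has its own seed recorded in the run config and stamped into the outputs;
  a rerun with the same config reproduces every file byte-for-byte. All
  engine-level randomness derives from R's RNG, so `set.seed()` governs
  everything.

## The synthetic-data generator

`covariance_spec()` defines a multivariate normal model
$\Sigma = \sigma^2 I + w A$ over a planted 0/1 adjacency $A$: planted edges
appear as correlations of $w/\sigma^2$, everything else is noise. If
$\Sigma$ is not positive definite the edge weight is uniformly shrunk with a
warning (preserving the planted edge ranking); a still-degenerate result is a
hard error naming the minimum eigenvalue. The generative family is Gaussian
because the pipeline consumes only Pearson correlations, making the marginal
shape irrelevant downstream. `planted_hub_adjacency()` composes a sparse
background graph with high-degree hub nodes, the scenario used to validate
hub detection and regional BC comparisons.

What the generator does *not* emulate: spatial autocorrelation of real
parcellations, site/scanner effects, age/sex trends (optional linear
residualization is provided but off by default, since covariance inputs in
the literature are not consistently covariate-adjusted), or non-Gaussian
volume distributions. Passing tests on synthetic data therefore demonstrate
correctness of the estimators and calibration of the inference, not
robustness to every property of real morphometry.

`clinical_spec()` mirrors the outcome table of a palliative epilepsy surgery
cohort: right-skewed (gamma) monthly seizure counts, a multiplicative
post-surgical reduction with additive noise floored at zero, Poisson-like
drug counts, and IQ/DQ scores perturbed between evaluations.

## Validation strategy and problem sizes

The test suite checks every metric against independent brute-force oracles
(Floyd–Warshall distances, dense matrix triangle counting, explicit
enumeration of all shortest paths, the modularity formula evaluated directly)
on a fixture suite of all labeled connected 4-node graphs plus structured and
random connected graphs up to 8 nodes, at tolerance 1e-9; igraph provides a
second, independent cross-check on larger random graphs. Calibration is
verified empirically: under the full null (both groups drawn from one
covariance spec, 20 subjects per group) the one-tailed test at α = 0.05
rejects in 2–9% of 200 repetitions; with a planted dominant hub (wired to 11
of 15 partner regions at the strongest positive-definite coupling, 100
subjects per group) the FDR-corrected regional BC comparison recovers the hub
with sensitivity ≥ 0.8 over 50 seeded runs. A planted hub's correlations are
capped near $0.95/\sqrt{\text{degree}}$ by positive definiteness, and
simultaneous hubs share shortest paths and depress each other's betweenness —
two constraints worth remembering when designing recovery simulations. The end-to-end check runs the full study shape — three groups of
21/21/32 subjects by 90 regions, 21 densities, all metrics, three contrasts
at 1000 permutations — which completes in well under 15 minutes on one CPU;
these sizes were chosen so the whole validation cycle stays comfortably
interactive.

## Known limitations

* Binary, undirected networks only; no weighted or signed-graph variants.
* Group-level networks mean no subject-level network statistics or
  covariate-adjusted group models; inference is purely permutation-based.
* σ is undefined at densities where the null ensemble has zero clustering or
  a disconnected null; such draws are discarded and counted rather than
  imputed.
* The generator's Gaussian, exchangeable-subject model cannot probe
  violations such as heavy-tailed volumes or subject outliers.

## A minimal worked example

```{r example, eval = FALSE}
region_names <- aal_region_names(90)
A <- planted_hub_adjacency(90, hub_nodes = c(5, 17), hub_degree = 8,
                           background_p = 0.06, seed = 1)
tabs <- list(
  pre = generate_group_volumes(covariance_spec(90, A, edge_weight = 0.25,
                                               seed = 11),
                               21, region_names, "pre"),
  post = generate_group_volumes(covariance_spec(90, A, edge_weight = 0.25,
                                                seed = 12),
                                21, region_names, "post"),
  control = generate_group_volumes(covariance_spec(90, A, edge_weight = 0.25,
                                                   seed = 13),
                                   32, region_names, "control")
)
res <- run_full_analysis(tabs, "covnet_results", run_config(seed = 1))
res$contrasts$pre_vs_post$global       # AUC differences and p-values
res$hubs$pre$at_mid_density            # BC hubs at the grid midpoint
```
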