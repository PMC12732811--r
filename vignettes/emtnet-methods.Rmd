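---
title: "Methods: consensus hub discovery and EMT-state analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus hub discovery and EMT-state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`emtnet` implements a multi-stage in-silico workflow for nominating and
validating regulators of the epithelial–mesenchymal transition (EMT) from
expression data: differential expression across several induction
experiments, DEG-restricted interaction networks scored by twelve
centrality metrics, a cross-network consensus hub rule, gene-set
enrichment (cohort-level and single-sample), a single-cell
classification stage, and patient-cohort correlation/survival analyses.
This vignette documents the statistical models, the conventions that had
to be pinned down, the tunable parameters, and what the synthetic-data
generators do and do not emulate.

## Differential expression

Input matrices are genes × samples on the log2 scale (raw matrices pass
through `log_normalize`, which applies `log2(x + 1)`). For two groups A and
B the effect is `log2FC = mean(A) − mean(B)` and the statistic is a
two-sided t test with pooled variance s² on d = n_A + n_B − 2 degrees of
freedom. With `moderated = TRUE` (the default) the gene-wise variances are
shrunk toward a common prior with the empirical-Bayes posterior

s̃²_g = (d₀·s₀² + d·s²_g) / (d₀ + d),

where the prior degrees of freedom d₀ and prior variance s₀² are
moment-matched from the observed distribution of log s²_g using the
digamma/trigamma moments of the log-chi-square distribution (a Newton
solver inverts the trigamma function). Two boundary conventions follow the
established empirical-Bayes practice and are verified against
`limma::eBayes` in the test suite: when the spread of log variances is no
larger than its sampling noise the prior df is infinite and s₀² is the
arithmetic mean of the variances, and the total df d + d₀ is capped at the
summed residual df across genes. A gene with identical values in both
groups gets t = 0, p = 1; a matrix in which *every* gene has zero
within-group variance is rejected as degenerate.

DEG selection uses an inclusive fold-change bound and a strict FDR bound
(|log2FC| ≥ 1.5 and BH-adjusted p < 0.05 for discovery; 1.0 is the
verification default and 0.5 the pseudobulk default), exactly as the
inequalities are printed. Duplicate gene symbols are collapsed to the
highest-variance row before testing, mirroring best-probe conventions.

## Networks and the twelve centralities

`build_network` keeps edges with confidence strictly above the cutoff
(default 0.7; scores on the 0–1000 STRING scale are divided by 1000, with
auto-detection overridable). When a DEG list is supplied as the node
universe, both endpoints must be members ("no additional interactions")
and the resulting node set *is* the universe, so DEGs without retained
interactions remain as zero-degree vertices. All metrics are computed on
the simple unweighted graph — confidence only filters — and networks are
never reduced to their largest component; instead every metric carries a
per-component or isolated-node convention:

* **Degree**; **MNC** = order of the largest component of the open
  neighborhood; **DMNC** = edges of that component divided by its order to
  the power ε (default 1.7; 0 when it has < 2 nodes); local
  **clustering coefficient** (0 for degree < 2).
* **MCC** = Σ over a node's maximal cliques of (|C| − 1)!, with maximal
  cliques enumerated exactly (Bron–Kerbosch with pivoting, via igraph) and
  a configurable enumeration budget; an isolated node scores 0.
* **Closeness** = Σ 1/d(v, w) with 1/∞ = 0; **EcCentricity** = reciprocal
  eccentricity (0 for an isolated node) — the reciprocal orientation is a
  convention this package fixes, so ranks may be oriented differently from
  other tools; **Radiality** uses the component's own diameter and order
  (0 for singletons); **Betweenness** and **Stress** sum over unordered
  pairs and are computed in a single Brandes-style pass that accumulates
  both the fractional and the raw shortest-path counts.
* **EPC**: K Monte-Carlo replicates (default 1000) retain each edge
  independently with probability 0.5; a node's score is the average number
  of vertices sharing its component, itself included, so an isolated node
  scores exactly 1. The replicate stream is seeded and reproducible. (A
  single-vertex graph therefore scores EPC = 1 while all other metrics are
  0 — the self-connectivity convention takes precedence.)
* **BottleNeck**: for every root s in a node's component a BFS
  shortest-path tree is built with deterministic parent tie-breaking
  (lexicographically smallest parent name); v scores one point per root
  whose tree gives it a subtree (itself included) larger than 1/4 of the
  tree, the root itself never scoring.

Every deterministic metric is validated exactly against an independent
brute-force oracle (exhaustive simple-path enumeration, subset-based clique
enumeration, explicit tree construction) on hundreds of random graphs of up
to 7 nodes, plus hand-derived fixtures.

## Consensus hub calling

Per network, `top_fraction_candidates` takes, for each of the twelve
metrics, the k = ⌈fraction × n⌉ top-scoring nodes (fraction defaults to
0.15) *plus any node tied with the k-th score*, and returns the union —
"top 15% by at least one metric". The ceiling-plus-ties rule is this
package's convention: a gene is never excluded by an arbitrary tie-break.
Note a consequence exercised in the tests: if a metric is constant across
all nodes, that metric contributes every node.

`consensus_hubs` counts candidate membership across networks; consensus
requires membership in ≥ `min_networks` (default 3, as in a 3-of-4
design). `annotate_direction` then collects each consensus gene's
*significant* signed calls across the datasets: unanimously positive →
up, unanimously negative → down, mixed → variable; genes with no
significant call anywhere are kept, labelled variable, and flagged rather
than silently dropped. The ranking universe of each network is its own
node set (the dataset's DEGs), not the genome.

## Enrichment

`gsea_preranked` walks the ranked list (descending metric, ties broken
lexicographically by symbol): hits add |r|^weight normalized over the
set's hits, misses subtract 1/(N − N_hit), and the enrichment score is the
signed maximum deviation, so a set occupying the top block scores exactly
+1 and the bottom block −1. The null is gene-label permutation: n_perm
random same-size placements (seeded), or the complete enumeration of all
C(N, N_hit) placements whenever that count is at most n_perm — in which
case the p value is exact. NES divides ES by the mean |null ES| of
matching sign; the sampled p uses the +1/(n+1) continuity convention.
`gsea_collection` filters sets to post-intersection sizes in [25, 500],
applies BH across the tested sets, and reports significance at the
nominal p < 0.05. The default weight is 1; weight 0 reduces to the
classical two-CDF Kolmogorov–Smirnov running sum, which the tests verify
against a direct oracle.

`ssgsea_scores` ranks genes per sample (descending expression, symbol
tie-break), weights hits by rank^α with α = 0.25 by default, and sums the
difference between the weighted cumulative hit distribution and the
uniform miss distribution; no cross-sample normalization is applied unless
requested (min–max switch). α = 0 gives uniform hit weights.

## Single-cell stage

Quality control keeps cells with *strictly* more than 200 and fewer than
5000 detected genes, more than 1000 UMIs and less than 5% mitochondrial
content (genes prefixed `MT-`); all four bounds are strict, following the
printed wording, and removal reasons are logged per cell. Normalization
scales each cell to 10⁴ counts and applies log1p; the 2000 most variable
normalized genes form the HVG set, z-scaled per gene for the embedding
only. PCA keeps 50 components with a deterministic sign convention
(largest-magnitude loading positive). Clustering runs seeded multilevel
modularity optimization (Louvain) at resolution 1 on the Euclidean kNN
graph (k = 20) in PC space — a documented, dependency-light stand-in for
SNN-based pipelines; exact agreement with any particular toolkit's
clustering is not claimed, and the cluster *count* is not a target
quantity. Labels are contiguous integers by decreasing cluster size.

Cluster classification computes per-cell ssGSEA scores for the epithelial,
mesenchymal and hallmark-EMT sets. The state call compares the cluster
mean of the per-cell *raw score difference* (mesenchymal − epithelial,
which is on a common scale by construction): positive → mesenchymal-like.
Per-set z-scores across cells are also reported — they are the relative
enrichments usually plotted per cluster — but they are not used for the
call, because z-scoring removes the absolute level of each score and would
make calls on a dataset containing only one state arbitrary; the raw
difference keeps such degenerate data on a single label. Pseudobulk DE
partitions each state's cells into 3 seeded random pseudo-replicates, sums
counts, converts to log2 counts-per-million with a +1 pseudocount, and
reuses the moderated two-group test with the 0.5/0.05 thresholds.

## Cohort stage

`marker_correlations` uses average-rank Spearman correlation with an exact
permutation p value for n < 10 (exhaustive over all n! orderings, so ties
are handled exactly) and the t approximation otherwise, BH-corrected
across markers. `extreme_groups` selects the top-k and bottom-k samples by
target expression (default k = 20) with deterministic sample-id
tie-breaking and a warning when ties cross a boundary; the extreme-group
contrast is then an ordinary two-group DE + GSEA reusing the bulk
machinery, not a separate count model. `median_split` puts samples at or
below the median in the low group — one convention had to be fixed; this
one is documented and symmetric-tested. `km_logrank` returns product-limit
curves per group (subjects censored at an event time count as at risk at
that time) and the asymptotic two-group log-rank χ² with hypergeometric
variance; the standard survival machinery stands behind this surface, with
degenerate inputs (no events, identical groups) mapped to χ² = 0, p = 1.

## Synthetic-data generators

Each generator takes an explicit seed (never global state) and returns its
ground truth alongside the data.

* **Bulk** (`make_bulk_expression`): microarray-like Gaussian noise on the
  log2 scale (the source experiments are microarrays), per-gene baselines
  uniform on log2 4–10, and a planted mean shift of exactly
  ±`lfc_magnitude` for the DE genes. The EMT marker panel (real symbols;
  epithelial down, mesenchymal up) is always among the planted DEGs so
  GMT fixtures stay meaningful. Defaults: 1000 genes, 5 + 5 samples, 100
  DEGs, effect 2, noise SD 0.5 — small-cohort microarray conditions.
* **Network** (`make_network`): preferential-attachment background
  (2 edges/node), disjoint dense hub modules (15 members at 90% pairwise
  wiring, hub connected to all members plus at least twice the median
  background degree of extra nodes), Beta(6, 2) confidence scores (mean
  0.75, so a 0.7 cutoff removes an appreciable fraction).
* **Single-cell** (`make_scrna`): negative-binomial counts with shared
  dispersion 0.5 and gene-specific means; two latent states whose mixture
  shifts across four timepoints (epithelial fraction 0.9 → 0.1, emulating
  an induction time course); 50-gene signatures per state up-shifted
  4-fold; healthy libraries log-normal around 2500 UMIs with ~1.5%
  mitochondrial content; planted low-quality cells alternate between
  low-library (200–600 UMIs) and high-mitochondrial (~15%) failure modes,
  so each violates at least one QC bound with near-certainty.
* **Cohort** (`make_cohort`): a standard-normal latent target; markers from
  a single-factor Gaussian copula with Pearson loading 2·sin(π·ρ_s/6) so
  the *Spearman* correlation hits the requested target (the factor
  construction is positive semidefinite by design; |ρ| > 1 is rejected);
  exponential event times with log-hazard linear in the latent target
  (`hazard_log_ratio` per SD of expression); independent exponential
  censoring whose rate is solved numerically so the expected censored
  fraction equals `censor_rate`.
* **Hub study** (`simulate_hub_study`): the multi-dataset scenario — one
  gene universe, named hub genes planted as upregulated DEGs in every
  dataset, one independently wired network per dataset in which the same
  hubs carry dense modules whose membership is re-randomized per network
  and planted as that dataset's DEGs. Recurrent centrality therefore
  isolates the hubs: module members are central only in their own
  network, and the shared marker panel is differentially expressed
  everywhere but carries no planted wiring.

What the generators deliberately do **not** emulate: probe-level
microarray artifacts, cross-platform batch effects, doublets, ambient
RNA, dropout structure beyond the negative binomial, or non-proportional
hazards. Passing tests therefore demonstrate that the algorithms recover
planted structure under idealized noise, not that any particular
biological dataset would yield the same gene lists.

## Numerical and reproducibility choices

* All stochastic stages (generators, EPC, GSEA permutations, clustering,
  pseudobulk partitions) take explicit seeds and restore the caller's RNG
  state.
* `run_all` writes every artifact as plain text; rerunning with the same
  configuration and seeds is byte-identical. Wall-clock timings are kept in
  the returned report object but excluded from the serialized JSON for that
  reason.
* Problem sizes used by the test suite and the acceptance script (for
  example 200 oracle graphs of ≤ 7 nodes, 20-seed hub-recovery studies of
  300-node networks, a 2000-cell single-cell run, 300–500 survival
  replicates) were chosen as the smallest sizes at which the binomial or
  Monte-Carlo tolerances of the checks are meaningful.
* Ties are broken deterministically everywhere (lexicographic symbols for
  rankings and BFS parents, sample ids for extreme groups); descending
  ranks share the minimum rank.

## Known limitations

Numerical equality with the external tools the workflow is modelled on
(GEO2R/limma runs with unknown settings, Cytoscape plugins, Seurat,
pseudobulk wrappers, web survival platforms) is not claimed: those tools
were used as black boxes in the original analyses and their exact
parameters are not published. The package pins every convention instead
and validates against independent oracles. The single-cell embedding is
for structure recovery, not visualization fidelity; no trajectory
inference, batch integration, Cox regression or multivariate adjustment is
provided.
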