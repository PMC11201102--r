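---
title: "Meta-analytic multi-omics gene clustering: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analytic multi-omics gene clustering: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the three gene-to-gene correlation measures, the fixed-effects pooling
model, the modified weighted-correlation-network clustering stage, and the
simulation model used to benchmark them. It also records the numerical and
design choices made where the procedure is genuinely underdetermined, and
what the synthetic benchmarks do and do not demonstrate about real data.

## 1. The estimation problem

Given K independent studies that each measure the same G genes on V omics
types over S_k matched samples, we want a partition of the genes into
clusters of mutually correlated genes. The package treats this as a
three-stage estimation problem: estimate a gene-to-gene correlation matrix
per study, pool the matrices across studies under a fixed-effects model,
and cluster the pooled matrix.

### Per-study correlation measures

Each gene in study k is summarized by its S_k × V gene-specific matrix
(samples × omics). For a pair of genes:

* **CC** (`method = "cc"`) is the first canonical correlation between the
  two genes' omics profiles — the largest Pearson correlation achievable
  between linear combinations of their columns. It is nonnegative and uses
  all cross-omics information jointly.
* **MOC** (`method = "moc"`) scans all V × V omics pairings and keeps the
  signed correlation of largest magnitude.
* **MSOC** (`method = "msoc"`, the default) scans only matching omics types.
  Its candidate set is a subset of MOC's, so |MSOC| ≤ |MOC| ≤ CC always
  holds (up to the CC ridge below). MSOC is the only measure computable
  when different omics types were assayed on disjoint samples.

All three reduce to the ordinary Pearson correlation (its absolute value,
for CC) when V = 1. With V = 1 matrices, MOC and MSOC *are* Pearson
correlations; with larger V the max-magnitude selection inflates weak
background correlations (an extreme-value effect that grows with the number
of candidates: V² for MOC, V for MSOC). This inflation, and the fact that
CC's maximization admits the best single pairing as a feasible point, drive
the empirical ordering of the methods in the benchmarks.

### Fixed-effects pooling

Stacking the p\* = G(G−1)/2 distinct pair correlations of study k into a
vector r_k, the model is r_k = ρ + e_k with e_k ~ N(0, T_k). The classical
asymptotic covariance of two sample correlations sharing one sample (the
Olkin–Siotani plug-in; see `correlation_covariance()`) fills T_k; its
diagonal is Var(r_ab) = (1 − r_ab²)² / S_k. Canonical correlations are
Pearson correlations of canonical variates and obey the same asymptotic
variance, so one covariance model serves all three measures. The GLS
estimator

ρ̂ = (Σ_k T_k⁻¹)⁻¹ Σ_k T_k⁻¹ r_k

is `combine_full()`; replacing T_k by its diagonal yields the entrywise
inverse-variance weighted mean, `combine_diagonal()`. The diagonal variant
costs O(K p\*) instead of O(K p\*³) and, at realistic sample sizes, is also
*more accurate downstream*: the p\* × p\* plug-in covariance is estimated
from the same S_k samples as r_k itself and is noisy enough that weighting
by it degrades the pooled matrix. This is visible in the benchmarks, where
the diagonal variant dominates the full one — the package therefore
defaults to `pool = "diagonal"`.

Pooling operates on **signed** MOC/MSOC values; the absolute value is taken
afterwards by `finalize_for_clustering()`. The alternative order (fold
first, pool after) would pool folded noise — |r| of a near-zero correlation
has positive mean — and bias weak background entries upward. The order is
exposed only through the function boundary: users who want to pool folded
values can finalize each study vector first.

## 2. The modified WGCNA stage

The pooled, finalized matrix (entries in [0, 1]) is raised elementwise to
an integer power m (`adjacency()`), converted to topological-overlap
similarity (`tom_similarity()`), and clustered by average-linkage
hierarchical clustering on 1 − TOM (`tom_cluster()`).

### Choosing the soft-threshold power

Mean connectivity k(m) — the average total adjacency of a gene — always
decreases in m. The traditional criterion picks the smallest m with
scale-free adjusted R² ≥ 0.6 and relative connectivity drop
(k(m−1) − k(m)) / k(m−1) ≤ 1/3. On the matrices this package produces, that
criterion routinely selects powers of 15–20, by which point the mean
connectivity is essentially zero and the clusterable structure has been
flattened.

The package's default rule works on the **change rate**
ρ(m) = (k(m) − k(m+1)) / k(m) instead. A structural point about k(m)
explains why: k(m) is (up to a factor) the m-th moment of the empirical
distribution of adjacency entries, hence a completely monotone sequence —
*every* finite difference of k(m) has a fixed sign, for any input matrix.
No rule phrased on raw differences of k(m) (second differences, third
differences, ...) can therefore ever find a local extremum. The change rate
ρ(m), in contrast, is a ratio: it always decreases (log-convexity of moment
sequences), but its own increments s(m) = ρ(m+1) − ρ(m) need not be
monotone. The rule selects the first grid power at which s attains a local
extremum — the first inflection of the change rate, which is where the
connectivity decay switches from "dominated by the bulk of weak entries"
to "dominated by the strong within-cluster entries". When s is monotone
over the whole grid (typical for noisy single-study matrices whose decay is
smooth), the rule takes the power at the grid maximizer of |s| — the knee
of the decay — rather than escalating to the traditional criterion's large
powers. On the pooled reference benchmark both branches land at m = 2–3
while the traditional criterion picks m ≈ 17.

Tunables: `grid` (default 1:20, integer powers — the power function is an
integer power), `r2_cutoff` (0.6) and `rate_cutoff` (1/3) for the
traditional rule, `n_bins` (10 equal-width connectivity bins; plain
adjusted R² of the log–log frequency fit, not a signed variant).

### Cutting the dendrogram

The procedure needs a cut height and a minimum cluster size; only the
latter has an established convention (here `min_cluster_size = 3` by
default, matching the smallest structure the reference benchmark plants
relative to its cluster size 5). For the cut itself the package uses a
deterministic, scale-free rule: sort the merge heights h, convert to merge
similarities 1 − h, and cut at the geometric midpoint of the largest
*relative* drop between consecutive merges. Two properties motivated it:

* On separable input (block-diagonal TOM) it recovers the blocks exactly.
* It is invariant to the compression of the dendrogram at high powers. At
  m = 15 all merge heights approach 1 and absolute gaps vanish, but the
  *ratios* of merge similarities still separate within-cluster from
  between-cluster merges; a cut based on absolute gaps (or on a quantile of
  merge heights, which lands inside the top cluster-joining merges whenever
  there are more clusters than (1 − q)·G) collapses there.

Clusters below the minimum size are dissolved and their genes reassigned to
the surviving cluster at smallest average dissimilarity (label 0 when
nothing survives); labels are renumbered by decreasing final size. The cut
policy, quantile alternative and numeric override are all exposed as the
`cut` argument.

## 3. The simulation model

`sim_config()` describes a G·V-variate normal with unit variances whose
correlation matrix encodes the planted structure (gene-major, omics-minor
variable order): τ1 between omics of the same gene, τ2 between the same
omics of different genes in one cluster, τ3 across omics and genes within a
cluster, τ4 between clusters, and a background level τ5 used for
perturbation. In a proportion p of the clusters, the first
`n_perturbed_genes` genes have their omics-1 correlations with the rest of
*their cluster* rewired to τ5 — emulating one omics type telling a
different story than the others for some genes.

The perturbation is confined to the gene's own cluster deliberately. The
cross-cluster omics-1 correlations already sit at τ4; forcing them to τ5 as
well makes the matrix indefinite whenever τ5 < τ4 (all the weak-signal
settings have τ4 = 0.2, τ5 = 0.1, and rewiring against all genes produces
smallest eigenvalues near −1), so no multivariate normal with that
"correlation matrix" exists. When τ4 = τ5 — every strong-signal setting —
the two formulations coincide entry-for-entry. Positive definiteness is
asserted at build time (smallest eigenvalue > 1e−10) and an invalid τ
combination fails loudly; there is no nearest-PD repair, because silently
moving the targets would change the study conditions.

The defaults — 50 genes in 10 clusters of 5, V = 3, K = 5 studies of
S_k = 100, τ = (0.6, 0.4, 0.3, 0.1, 0.1), p = 0.3 with 3 rewired genes per
perturbed cluster — are the reference conditions used by the package's
benchmarks, chosen as a realistic strong-signal regime: within-gene
correlation strongest, within-cluster correlations clearly above the weak
between-cluster level that real co-expression backgrounds show.

What the simulator does **not** emulate: non-Gaussian marginals and count
overdispersion (RNA-seq), heteroscedastic genes, gene-specific correlation
levels, missing-by-design omics blocks, and batch effects. Perfect ARI on
these benchmarks therefore demonstrates correctness of the estimation
machinery under its own model, not performance on raw sequencing data —
real inputs should be normalized upstream (the package deliberately has no
normalization or imputation step; genes with missing values are dropped at
load time and studies are aligned by sorted gene-identifier intersection).

## 4. Evaluation harness

`run_scenario()` replicates a scenario end-to-end: simulate K studies,
compute the requested methods (pooled variants, single-study variants,
single-omics WGCNA baselines on omics 1 of study 1 with either power rule,
and optional K-means comparators), and score each against the planted
clusters with the adjusted Rand index (`adjusted_rand_index()`, the
Hubert–Arabie form: 1 for identical partitions, expectation 0 under random
labeling). Everything is driven by one master seed: per-replicate and
per-study seeds are drawn deterministically from it, so runs are
bit-reproducible.

The package's test and acceptance runs use 20 replicates of the reference
conditions (the harness default is 100); at 20 replicates the mean ARIs are
stable but standard deviations are wide, and the "smallest number of
studies with perfect mean ARI" statistic can move by one between seeds when
a single replicate at a given study count is imperfect.

## 5. Numerical choices

* **CC ridge.** Within-gene covariances get ridge ε = 1e−8 · trace/V before
  whitening, so collinear omics profiles (duplicated assays, constant
  genes) do not break the Cholesky factor. On well-conditioned input the
  first canonical correlation is unchanged to ~1e−6.
* **Weight clipping.** Correlations are clipped to |r| ≤ 1 − 1e−6 before
  the variance formula, keeping inverse-variance weights finite when a
  simulated correlation reaches ±1.
* **Indefinite T_k.** The plug-in covariance is asymptotic and can be
  indefinite at finite S_k. `combine_full()` repairs it with an escalating
  diagonal ridge (starting at 1e−8 of the mean diagonal, ×10 per attempt,
  capped), then factorizes; all solves are Cholesky-based, never explicit
  inverses. The repair is detectable in the ridge magnitude but was never
  needed beyond the first step in the benchmarks.
* **Memory guard.** The full variant stores a p\* × p\* matrix per study;
  `max_genes` (default 200) refuses larger problems unless forced.
* **Zero-variance columns** correlate as 0 with a warning rather than NaN.
* **Ties.** Max-magnitude selection (MOC/MSOC) takes the first candidate in
  a fixed scan order; cluster renumbering breaks size ties by original
  label — the pipeline contains no randomness.

## 6. Known limitations

* Correlation-based clusters do not imply causal or regulatory links.
* The fixed-effects model assumes one common ρ across studies; there is no
  random-effects extension or heterogeneity test, so genuinely conflicting
  studies are averaged, not flagged.
* V must be constant across genes within a study; studies enter with equal
  weight structure regardless of quality beyond sample size.
* The full-GLS variant is quartic in G in memory and is practical only for
  gene panels of a few hundred genes.
* The single-omics baselines and comparators (WGCNA variants, K-means with
  the gap statistic) are included for benchmarking, not as supported
  analysis paths.
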