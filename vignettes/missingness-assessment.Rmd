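---
title: "Assessing missingness in DIA/SWATH protein matrices with protmiss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing missingness in DIA/SWATH protein matrices with protmiss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protmiss)
```

## Scope and assumptions

`protmiss` operates on protein-level quantitation matrices (samples ×
proteins) whose values are assumed **already log-transformed** — the
typical output of an upstream MSstats-style pipeline. Nothing is
transformed on load; a `log2` flag on `load_matrix()` exists for
raw-scale input. Missing cells are represented explicitly: a
`ProteinMatrix` carries the value grid (with `NA` at missing cells) and
a logical mask, and every function treats the mask, not a sentinel
value, as the source of truth. Accepted missing-value encodings on disk
default to `""`, `"NA"`, `"NaN"`, `"null"`; the field has no standard,
so the set is exposed as an argument.

The package takes no position on whether a dataset's missingness is
MAR or MNAR — that question is usually unanswerable from the data
alone. Instead it quantifies how strongly each *assumption* (an MNAR
imputer versus MAR imputers) distorts the observable distributions at
each missingness threshold, so the analyst can pick a
threshold/method combination with known consequences.

## Imputation engines

All five engines satisfy two contracts: observed cells are returned
bit-for-bit unchanged, and the completed matrix has no missing cells.

* **Lowest value** (MNAR). Every missing cell becomes the constant
  `fill = 1` — the lowest possible value on a log-transformed intensity
  scale, encoding the belief that the protein fell below the detection
  limit. Because some practitioners read "lowest value" as the dataset
  minimum instead, `use_observed_min = TRUE` substitutes the global
  observed minimum. Deterministic.
* **Chained equations** (MAR). Missing cells start at observed column
  means; each sweep regresses every incomplete protein on all others
  (ridge-regularised least squares, penalty `1e-3` × the mean diagonal
  of the predictor cross-product — large enough to keep the normal
  equations well-posed when proteins outnumber samples, small enough
  not to bias a clean linear signal) over the samples where the target
  was genuinely observed, then refreshes its missing cells with the
  conditional means plus, by default, a seeded draw of Gaussian
  residual noise as in standard chained-equations practice.
  `deterministic = TRUE` suppresses the noise for exact testability.
  Default 10 sweeps.
* **Iterative forest** (MAR). The missForest scheme: proteins visited
  in order of increasing missingness, each predicted by a random
  forest (`randomForest`, 100 trees by default) on the other proteins;
  rounds stop at the first increase of the normalised change in
  imputed values, returning the previous round (default cap 10
  rounds).
* **PPCA** (MAR). Probabilistic PCA — Gaussian latent factors plus
  isotropic noise — fitted by an EM scheme for incomplete data:
  mean-fill, fit by eigendecomposition (the complete-data ML
  solution), replace missing cells with the posterior-mean
  reconstruction `μ + W(WᵀW + σ²I)⁻¹Wᵀ(x − μ)`, repeat. Converges when
  the maximum relative change of the imputed cells drops below
  `tol = 1e-6` (cap 500 iterations); non-convergence returns the
  result with `converged = FALSE` and a warning rather than an error.
  On noise-free low-rank data the fixed point reproduces the
  generating values, which the tests exploit.
* **EM** (MAR). A multivariate normal over proteins fitted by
  expectation-maximisation with proper conditional covariance terms in
  the M-step; final missing cells are conditional expectations given
  the sample's observed cells. The covariance receives a ridge of
  `1e-6` × its mean diagonal every iteration so the model remains
  usable when proteins outnumber samples (the matrices this package
  targets usually have that shape); a covariance still singular after
  regularisation is a hard error that names the remedy (raise the
  threshold or switch methods).

Model-based engines refuse proteins with zero observed values (there
is nothing to condition on); lowest-value accepts them.

## Threshold exploration

`filter_by_threshold(m, tau)` keeps exactly the proteins whose missing
fraction is **strictly below** τ. The strictness matters: τ = 1 still
drops a fully missing protein, and τ = 0 keeps nothing (legal, and
rejected explicitly by downstream consumers). Whole-cohort comparisons
are densities of **per-sample mean observed intensity** — not pooled
protein values — because a per-sample summary is what cohort-level
density plots show in practice; the single-protein view pools that
protein's values across samples. The filtering for both matrices uses
the *non-imputed* missing fractions, so the imputed and non-imputed
views always describe the same protein set. The percentage of missing
values is reported both after filtering (what the comparison actually
sees) and before (the dataset-level figure), since either reading is
defensible.

Densities use a Gaussian kernel on a 512-point grid spanning
[min − 3h, max + 3h], bandwidth h by Silverman's rule of thumb unless
overridden. Two numerical choices are worth stating. First, the
returned curve is renormalised by its trapezoid integral: with a hard
grid cut at ±3h each edge kernel loses ≈ 0.13% of its mass per side,
which is invisible for realistic n but would violate the
integrates-to-one contract for very small vectors. Renormalisation
affects no peak location. Second, the peak is the grid argmax with
ties broken towards the smallest grid value — a documented convention,
not an estimate of anything. A constant input yields a spike at the
constant with a warning.

The two-sample Kolmogorov–Smirnov statistic is computed directly as
the supremum of |ECDF_x − ECDF_y| over the pooled order statistics
(ties handled by evaluating at the right edge of each tie group); the
p-value uses the asymptotic Kolmogorov series at √(n_eff)·D with
n_eff = nm/(n+m), truncated at 100 terms, with an exact small-sample
option delegating to `stats::ks.test(exact = TRUE)`. The direct D is
contracted against a brute-force breakpoint enumeration to 1e-12 in
the tests.

## The Mapper construction

`build_mapper()` composes: distance matrix → two lenses → overlapping
2-D cover → per-bin single-linkage clustering → nerve graph.

* **Distances.** Euclidean on sample rows. With missing values the
  default policy computes the distance over the k co-observed proteins
  and rescales by √(p/k) — the classical available-case correction
  (this is exactly `stats::dist`'s NA behaviour, which the package
  uses). A sample pair with k = 0 is a hard error naming the pair;
  `complete_only` instead drops incomplete samples and reports them.
  How missing values should enter a Mapper metric is genuinely open;
  both policies are provided and recorded in the run configuration.
* **Lenses.** L∞ eccentricity (each sample's maximum distance to any
  other) and the first PPCA component score by default. The published
  dashboards this mirrors name the first lens "L1 Infinity
  Centrality", which conflates two norms; this package defaults to the
  L∞ reading and ships an L1 (mean-distance) eccentricity variant for
  the other reading. The PPCA lens sign is fixed so scores correlate
  positively with per-sample mean intensity, making runs comparable.
* **Cover.** Per axis, n equal-length intervals spanning [min, max]
  with fractional overlap g: length L = range / (n − (n−1)g), interval
  i starting at min + i·L·(1−g); the 2-D cover is the cross product.
  Membership is closed on both ends and the last interval's upper edge
  is pinned exactly to the axis maximum, so the maximum always belongs
  to the last interval even under floating-point rounding. Defaults
  (16, 15) intervals and g = 0.5 reproduce a typical published
  configuration; "resolution" and "gain" sliders of interactive tools
  map to `intervals` and `overlap`.
* **Clustering.** Single linkage within each bin's pre-image, cut by
  the histogram-gap heuristic: merge heights are binned into
  `clustering_bins` (default 10, matching the published
  "single-linkage parameter = 10") equal-width bins over
  [0, max height], and the dendrogram is cut at the lower edge of the
  first **empty bin that follows an occupied one**. The qualifier is a
  deliberate design choice: the heuristic exists to find a gap
  *between* merge heights, and without it a bin of identical distances
  (all merges in the top bin, all lower bins empty) would shatter into
  singletons instead of remaining one cluster. No gap → one cluster.
* **Graph.** One node per cluster; an edge wherever two nodes share a
  sample; identical member sets within the same bin collapse. Node
  enrichment is the mean per-sample missing percentage of the node's
  members, always taken from the non-imputed profile. Communities
  maximise modularity — exactly (integer programming via
  `igraph::cluster_optimal`) for graphs of ≤ 12 nodes, greedy
  agglomeration beyond; an edgeless graph is defined to have
  singleton communities and modularity 0. Two topologies are compared
  by the adjusted Rand index between the sample partitions induced by
  assigning each sample to its largest containing node (ties to the
  earlier node).

Determinism: given identical inputs and seed, the construction is
bit-reproducible including node order (bins in cover order, clusters
by first member). Layout in plots is seeded but cosmetic.

## The synthetic generator

`simulate_dataset()` draws truth = baseline + per-protein means
(SD `protein_sd`) + per-sample offsets (SD `sample_sd`) + subgroup
shifts + per-batch×protein offsets + a rank-`rank` latent signal +
Gaussian noise, then masks in three layers, each cell labelled by its
mechanism: MNAR (cells below the global `detection_quantile` of truth
censored with probability `mnar_fraction / detection_quantile`, so
censoring is probabilistic and censored/observed values overlap, as in
real left-censoring), MCAR (uniform Bernoulli on the remainder), and
MAR (extra dropout in the second half of the batches).

`ckd_like_preset()` freezes a regime resembling a large, heavily
missing clinical plasma cohort: baseline 14 on the log2 scale,
per-protein SD 4, per-sample SD 0.45, `mnar_fraction = 0.56` below the
0.60 truth quantile, no MCAR/MAR. The per-protein SD is the one
parameter where a plausible-sounding smaller value fails: with SD 2
essentially no protein stays complete across 410 samples under
probabilistic censoring, whereas real cohorts of this kind retain
roughly a tenth of proteins complete; SD 4 reproduces that. The preset
yields ≈ 56% missing overall, per-sample fractions ≈ 0.41–0.68 and
≈ 11–17% complete proteins depending on size and seed. These values
were fixed once, before being wired into any assertion, and are not
tuned per run.

What the generator does **not** emulate: peptide-to-protein roll-up,
retention-time structure, heavy-tailed or multimodal protein
distributions, correlated (non-low-rank) biology, missingness that
depends on covariates other than intensity and batch. Tests passing on
this generator therefore demonstrate the *mechanics* of the pipeline
(contracts, invariants, the direction of MNAR bias), not performance
claims about any real cohort.

## Problem sizes and runtime choices

The bundled small preset is 100 × 200; test fixtures range from 2 × 2
edge cases to 300-sample regression fixtures; Mapper oracle fixtures
use ≤ 12 samples so a directly coded brute-force Mapper stays
readable; exhaustive modularity checks stop at 8 nodes (4,140
partitions). These sizes were chosen so the full suite runs in well
under a minute while every contract is still exercised at a
non-trivial scale; the same code runs the 410 × 899 preset in minutes.

## Known limitations

* The chained-equations engine is single imputation (optionally with
  noise); it does not pool multiple imputations.
* No RMSE-style benchmarking of imputation accuracy against withheld
  truth is exposed as a user-facing feature — with real data there is
  no truth to withhold; the test suite does it on synthetic fixtures
  where truth exists, and the acceptance script reports one such RMSE.
* Mapper output is sensitive to its resolution parameters, and the
  stability of Mapper summaries is an open research question; the
  package makes runs *reproducible*, not *stable*.
* The asymptotic KS p-value is approximate below ~10 observations per
  group; use `exact = TRUE` there.
* `complete_only` distances can silently shrink the sample universe of
  the non-imputed topology; the dropped samples are reported and the
  comparison is made on shared samples only.
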