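# protmiss

Missingness assessment, imputation and topology comparison for
protein-level quantitation matrices from data-independent acquisition
(DIA/SWATH) mass spectrometry.

## The problem

Protein matrices from DIA/SWATH experiments routinely arrive with half
their cells empty. Missingness mixes two mechanisms: values *missing at
random* (MAR, e.g. batch effects and technical losses) and values
*missing not at random* (MNAR, intensities left-censored below the
instrument's detection sensitivity). Before any downstream statistics,
an analyst must pick a missingness threshold τ (drop proteins with a
missing fraction ≥ τ) and an imputation method — and both choices can
reshape the protein distributions. `protmiss` makes that assessment
scriptable and reproducible for analysts of clinical proteomic cohorts.

## What it computes

* **Profiling** — per-sample and per-protein missing counts/fractions,
  overall missing fraction, complete-protein count, histogram bins
  (`profile_missingness()`).
* **Imputation** — five engines behind one dispatcher (`impute()`):
  `lowest_value` (MNAR: every missing cell ← a fixed low value, default
  1, the lowest possible value on a log scale), `chained_equations`
  (MICE-style ridge-regression cycling), `iterative_forest`
  (missForest-style random-forest rounds with the standard
  first-increase stopping rule), `ppca` (probabilistic PCA fitted by
  EM; missing cells ← posterior-mean reconstruction) and `em`
  (multivariate-normal EM; missing cells ← conditional expectations
  given the observed cells of the same sample). All engines preserve
  observed cells exactly.
* **Threshold exploration** — at each τ, both matrices are restricted
  to proteins with missing fraction < τ, per-sample mean intensities
  are compared via Gaussian KDE (Silverman bandwidth), density peaks
  (argmax) and their distance, quartiles, and the two-sample
  Kolmogorov–Smirnov statistic
  D = sup_t |F̂_x(t) − F̂_y(t)| with the asymptotic Kolmogorov p-value
  at √(n_eff)·D, n_eff = nm/(n+m)
  (`compare_at_threshold()`, `threshold_sweep()`, `compare_protein()`).
* **Topology (Mapper)** — a from-scratch two-lens Mapper
  (`build_mapper()`): Euclidean distances (pairwise-complete rescaled
  by √(p/k) when values are missing), lenses L∞ eccentricity and the
  first PPCA component, an overlapping 2-D interval cover (interval
  length L = range / (n − (n−1)g) at overlap g), single-linkage
  clustering of each bin pre-image with a histogram-gap cut, nerve
  edges between clusters sharing samples, per-node missingness
  enrichment (`enrich_missingness()`), modularity communities — exact
  for ≤ 12 nodes (`detect_communities()`) — and adjusted-Rand
  comparison of two topologies (`compare_topologies()`).
* **Synthetic data** — `simulate_dataset()` draws log2-scale matrices
  with a low-rank signal, subgroups, batch effects and controllable
  MCAR/MAR/MNAR masks; `ckd_like_preset()` freezes a regime resembling
  a heavily missing clinical plasma cohort (~56% missing overall).
* **Reports** — `run_report()` executes profile → impute → sweep →
  Mapper and writes CSV/JSON tables, GraphML graphs, PNG figures and a
  static HTML page; a CLI lives at
  `system.file("cli", "protmiss.R", package = "protmiss")` with
  subcommands `simulate | profile | impute | compare | tda | report`.

## Worked example

```r
library(protmiss)

sim <- simulate_dataset(ckd_like_preset("small"))   # 100 x 200, seed 101
m   <- sim$observed

profile_missingness(m)
#> MissingnessProfile
#>   overall missing:     0.5598 (56.0%)
#>   per-sample range:    0.4750 - 0.6600
#>   complete proteins:   34 of 200

low <- impute(m, "lowest_value")
compare_at_threshold(m, low$completed, 0.8)
#> ThresholdComparison (tau = 0.80)
#>   proteins kept:       101
#>   % missing (non-imp): 21.1584
#>   peaks: non-imp 17.7100, imputed 14.4979 (distance 3.2121)
#>   KS: D = 1.0000, p = 7.44e-44

compare_at_threshold(m, low$completed, 0.2)
#> ThresholdComparison (tau = 0.20)
#>   proteins kept:       62
#>   % missing (non-imp): 3.7581
#>   peaks: non-imp 18.3136, imputed 18.3465 (distance 0.0328)
#>   KS: D = 0.3700, p = 2.267e-06

mar <- impute(m, "chained_equations", seed = 7)
compare_at_threshold(m, mar$completed, 0.8)
#> ThresholdComparison (tau = 0.80)
#>   proteins kept:       101
#>   % missing (non-imp): 21.1584
#>   peaks: non-imp 17.7100, imputed 17.0964 (distance 0.6136)
#>   KS: D = 0.7100, p = 2.56e-22
```

Read: on left-censored (MNAR) data, lowest-value imputation drags the
density peak 3.2 log2 units left at a permissive threshold (τ = 0.8),
and the bias almost vanishes once highly missing proteins are removed
(τ = 0.2, distance 0.03). A MAR-style imputer (chained equations) at
the same permissive threshold distorts the cohort distribution far
less (KS D 0.71 vs 1.00, peak distance 0.61) — exactly the trade-off
the threshold/method exploration is meant to expose.

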