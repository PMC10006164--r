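---
title: "Local synthetic avatars for tabular data: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local synthetic avatars for tabular data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avatarize)
```

## The generative model

`avatarize` treats anonymization as a *local* simulation problem. Rather
than fitting one global generative model of the joint distribution, each
original record is the seed of its own miniature model: the empirical
cloud of its k nearest neighbors in a shared Euclidean embedding. The
avatar of record *O* is a random convex combination of those neighbors.
Three properties follow directly from the construction:

* avatars never extrapolate — they lie in the convex hull of k observed
  neighbors, so marginal supports and local correlation structure are
  respected;
* the record itself is excluded from its own neighborhood, so *O* never
  contributes to the model that simulates its avatar — proximity of the
  avatar to *O* is an emergent property of local density, not a copy;
* every avatar has a well-defined originating record, which is what makes
  record-level privacy metrics (local cloaking, hidden rate) computable at
  all. Global generators have no such linkage and can only be audited in
  aggregate.

### The embedding

All variable types are mapped into one Euclidean space by factor analysis
of mixed data (FAMD). Continuous and date columns are standardized to mean
0 / SD 1 (dates are first embedded as integer days since 1970-01-01, a
monotone transform that preserves distances). Each categorical level
(booleans are two-level categoricals) is one-hot encoded, divided by the
square root of its proportion and centered. The axes are the right
singular vectors of the encoded matrix. This is the standard construction:
with only continuous columns it *is* PCA on z-scores, with only
categorical columns it reproduces multiple correspondence analysis up to a
per-component scaling; both reductions are pinned by tests against
independent oracles.

Standardization before the decomposition is a deliberate choice (a library
default could equally have skipped it): without it, the variable with the
largest numeric range silently dominates every neighborhood.

The model always retains **full rank**. Truncation is applied only to the
*neighbor search*, never to the reconstruction, so the inverse transform
is exact: coordinates times the transposed axes, un-scaled, un-centered,
with each categorical set to the level of largest reconstructed indicator.
The full-rank round trip recovers continuous values to within 1e-8
relative error and categoricals exactly, and pairwise distances on scores
equal distances in encoded space to the same tolerance — so neighbor
search on coordinates is neighbor search on the data.

### The weight draw

Given the k neighbor distances d₁ ≤ … ≤ d_k, neighbor i receives

P_i = (1/d_i) · R_i · (1/2)^(j_i),  W_i = P_i / Σ P_j,

with R_i ~ Exponential(λ = 1) and (j₁,…,j_k) a uniformly shuffled
permutation of 1…k. The three factors play distinct roles: the inverse
distance anchors the avatar to the local geometry (nearer neighbors are
heavier on average), the shuffled halving contributions guarantee that in
*every* draw a few neighbors dominate (the weights cannot collapse to a
near-uniform average, which would shrink all avatars toward local
centroids), and the exponential factor injects the per-draw randomness
that makes the generator stochastic. The normalized weights are a convex
combination by construction: non-negative, summing to one, each ≤ 1.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 20 | neighborhood size. Small k: high fidelity, lower privacy; large k: neighborhoods span clusters, structure fades, privacy rises. |
| `nd` | `"auto"` | components used for the neighbor *search* only. `"auto"` picks the smallest count reaching 90% cumulative explained variance — enough geometry to define neighborhoods while avoiding distance concentration in high dimension. Recorded in the run manifest. |
| `distance` | euclidean | `mahalanobis` is implemented as Euclidean distance on variance-standardized component scores, which is its definition in an orthogonal factor basis. |
| `contribution_law` | halving | `equal` replaces the shuffled (1/2)^j contributions by 1, giving smoother, more centroid-like avatars. |
| `exponential_rate` | 1 | λ of the random factor. |
| `column_weights` | 1 each | per-variable multipliers of the encoded columns; upweighting a variable makes neighborhoods (and hence avatars) more faithful to it. |
| `perturbation_level` | 0 | experimental, see below. |
| `seed` | — | drives every draw of a run; fixed draw order (per row: shuffle, then the exponential factors; then one output permutation), so runs are bit-reproducible. |

### Numerical and degenerate-input choices

* **Zero distances.** Real tables contain exact duplicates, which make the
  inverse distance undefined. Distances are floored at
  `1e-9 × median positive pairwise distance` of the search space, so a
  duplicate neighbor gets the largest finite weight — "nearer means
  heavier" degenerates gracefully instead of failing.
* **Ties.** Neighbor ties break toward the lower row index; categorical
  decoding ties break toward the higher training proportion, then label
  order. Both rules are deterministic so fixed seeds reproduce runs
  exactly.
* **Zero-variance continuous columns and single-level (or unobserved-level)
  categoricals** are typed errors at fit time: they cannot be standardized
  or scaled, and silently dropping them would change the schema contract.
* **Missing values are rejected**, with the offending row and column
  named. Imputation is out of scope and conflating it with generation
  would blur what the privacy metrics measure.
* **NNDR conventions.** If the second-nearest real distance is zero (the
  synthetic point coincides with duplicated real records) the ratio is
  defined as 1, the maximally non-isolated reading. A synthetic record
  coinciding with exactly one real record has ratio 0 — an identity
  "generator" therefore scores NNDR 0, not 1, which is the definition
  taken at face value.
* **Local cloaking uses strict inequality**: an avatar tied in distance
  with the own avatar does not hide the individual. This is the
  conservative choice for the attacker and is deterministic under
  duplicates.

### The perturbation parameter

A per-variable "percentage of perturbation" is part of the method's
parameter surface but has no published definition. It is implemented here
as convex shrinkage of the avatar's encoded values toward the unweighted
neighbor centroid (per variable, level α ∈ [0, 1]), defaults to 0, and is
flagged experimental: the reading is this package's placeholder, not an
established semantic.

## The metric space

DCR, NNDR and local cloaking are computed in the **full-rank FAMD space
fitted on the original data**, with synthetic records projected into it by
the stored centers and scales. The alternative (raw standardized
variables) differs only by an orthonormal rotation on full rank, but a
single declared space keeps holdout baselines and cross-method
comparisons coherent; the space descriptor is recorded in every report.
Absolute DCR values depend on this choice and on p, so DCR should be read
against the holdout baseline computed in the same space, not as an
absolute.

## What the fixtures emulate — and what they do not

The package is exercised end to end on seeded generators:

* `generate_mixed()` — Gaussian-mixture clusters with cluster-tilted
  categoricals and optional exact duplicates: the cluster-plus-outlier
  geometry cohorts show in factor projections, and the duplicate pathology
  that drives DCR toward zero on low-variance data.
* `generate_survival()` — a two-arm trial with exponential event times at
  a known hazard ratio (default 0.5, n = 2000) and independent
  Uniform(0, b) censoring, b calibrated by root finding to the target
  censoring fraction (default 20%).
* `generate_classification()` — 1–10 integer-graded features (Gaussian
  draws, rounded and clipped) with class separation set per feature, plus
  an optional perfectly separating feature; effect sizes default to a
  graded ladder so F-score ranking is checkable.

These fixtures have known truth, which is what the tests need, but they
are far simpler than real biomedical tables: no informative censoring, no
missingness, no rare categories, no mixed measurement scales within a
variable, no dependence between the survival outcome and the covariates.
Passing tests demonstrate that the machinery is correct and that the
documented qualitative behaviors (hazard-ratio preservation, cloaking
growth with k, avatar DCR below the holdout baseline on clustered data)
hold under controlled conditions — not that any particular real dataset
is safe to release at a given k.

## Protocol and test problem sizes

The experiment protocols default to the designs they formalize: 25
repeated avatarizations for the re-identification stochasticity histogram,
10 runs per k in sweeps, 10 samplings of 70% for the DCR/NNDR protocol,
100 stratified 70/30 splits for the SVM comparison. The test suite and the
acceptance script run these designs on fixture sizes chosen to make every
check statistically meaningful yet desk-scale: n = 1000 (10 runs per k ∈
{5, 20, 50}) for the cloaking monotonicity property, n = 2000 × 10
replicates for hazard-ratio recovery, 50 brute-force oracle instances with
n ≤ 500 for the metric kernels. Seeds are split additively (run r of a
protocol uses `base_seed + r - 1`, sweeps offset by 1000 per k, sampling
seeds by 500000) so extending a study never perturbs completed runs.

## Known limitations

* Exact (brute-force) neighbor search is quadratic in n — appropriate for
  the cohort sizes targeted (10³–10⁴ rows), not for millions of rows.
* The FAMD embedding is linear; strongly curved manifolds are flattened,
  and the method inherits every limitation of the projection it uses.
  The projection interface is deliberately small (fit / transform /
  inverse) so an alternative embedding can be slotted in.
* Categorical decoding by argmax discards within-neighborhood category
  mixtures; rare levels are under-produced at large k.
* The privacy metrics quantify distance-based linkage attacks only; they
  are not a differential-privacy guarantee, and attribute-inference
  attacks are out of scope.
* k is uniform across records; dense and sparse regions might warrant
  adaptive neighborhoods.
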