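# avatarize

Patient-centric synthetic data generation and privacy auditing for
mixed-type tabular data.

## The problem

Pseudonymized biomedical tables — clinical trials, registries,
observational cohorts — still carry a re-identification risk: removing
direct identifiers does not stop distance-based linkage attacks. One way to
share such data safely is to replace every record with a *synthetic* record
that preserves the dataset's statistical structure while severing the link
to any real individual. `avatarize` implements a local, per-record
generator of such data and, crucially, the metrics needed to audit how well
each individual is actually protected.

## The method

Given an n × p table of continuous, categorical, boolean and date columns:

1. **Projection.** All columns are embedded in one Euclidean space by
   factor analysis of mixed data (FAMD): continuous columns are z-scored,
   each categorical level is one-hot encoded with indicators scaled by
   1/√(proportion) and centered, and the axes are the right singular
   vectors of the encoded matrix. The model keeps full rank, so the
   inverse transform is exact.
2. **Local model.** For each record *O*, its *k* nearest neighbors are
   found (exact search) in the leading *nd* components. Neighbor *i*
   receives a raw weight

   P_i = D_i × R_i × C_i,   i = 1…k,

   with D_i the inverse of the distance to neighbor *i*, R_i an
   Exponential(λ = 1) random factor, and C_i = (1/2)^(j_i) a contribution
   where (j_1,…,j_k) is a uniformly shuffled permutation of (1,…,k).
   Weights are normalized, W_i = P_i / Σ_j P_j.
3. **Generation.** The avatar of *O* is placed at the weighted center
   Σ W_i x_i of its neighbors' full-rank coordinates (a convex
   combination, so avatars live inside the local data envelope), decoded
   back to schema values by the inverse projection, and the output rows
   are shuffled.

Because each avatar originates from one record, privacy is auditable per
individual:

* **DCR** — distance of each synthetic record to its closest real record;
* **NNDR** — ratio of the nearest to second-nearest real-record distance
  (in [0, 1], higher = less isolated);
* **local cloaking** — how many *other* avatars are strictly closer to an
  original record than its own avatar (0 ⇒ a nearest-avatar linkage attack
  finds the true avatar);
* **hidden rate** — the percentage of records with local cloaking ≥ 1,
  i.e. the probability such an attack is wrong.

The utility harness compares original and synthetic data by FAMD overlay,
two-arm survival analysis (Kaplan-Meier, log-rank, Cox hazard ratio with
Wald test) and F-score-ranked radial-SVM classification (AUC), and the
experiment protocols (repeated avatarization, k sweeps, the 10 × 70/30
DCR/NNDR protocol with a holdout baseline) wrap these into seeded,
reproducible studies.

## Worked example

```r
library(avatarize)

ds <- generate_mixed(n = 500, seed = 7)              # 2-cluster mixed fixture
av <- generate_avatars(ds, avatar_config(k = 20, seed = 42))
privacy_report(ds, av)
#> <privacy_report>
#>   DCR    median 0.09584  [q05 0.02677, q95 0.1982]
#>   NNDR   median 0.7542  [q05 0.2393, q95 0.9809]
#>   local cloaking median 19
#>   hidden rate 96.4%
```

Avatars sit close to the data cloud (small DCR) but are not isolated next
to a unique original (NNDR well above 0), and for the median individual 19
other avatars are closer to them than their own — a linkage attack picks
the wrong avatar for 96.4% of records.

```r
surv <- generate_survival(n = 2000, hr = 0.5, seed = 7)   # true HR = 0.5
survival_comparison(surv, "time", "event", "arm")
#> HR (1 vs 0) = 0.498 [95% CI 0.451-0.551], Wald p = 5.57e-42, log-rank p = 0

av2 <- generate_avatars(surv, avatar_config(k = 20, seed = 42))
survival_comparison(av2$data, "time", "event", "arm")
#> HR (1 vs 0) = 0.444 [95% CI 0.401-0.492], Wald p = 1.13e-54, log-rank p = 0
```

The avatarized trial reproduces the treatment effect: the avatar-data
confidence interval overlaps the original one and leads to the same
conclusion.

A file-based run (CSV in, CSV + JSON report out) is one call —
`avatarize("X.csv", avatar_config(k = 20, seed = 1), output = "X_avatar.csv")`
— or one shell command via the thin CLI in `inst/cli/avatarize.R`
(subcommands `run`, `metrics`, `fixture`).

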