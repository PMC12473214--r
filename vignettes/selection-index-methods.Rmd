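---
title: "A PCA-based composite selection index for multi-trait alfalfa breeding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCA-based composite selection index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alfaselect)
```

## The problem

Forage yield in alfalfa (*Medicago sativa* L.) is a network of interacting
traits, not a single measurement: biomass correlates positively with plant
height and branching, and trades off against moisture retention (the
fresh/hay ratio, FHR). Selecting hybrids on any single trait ignores those
correlations and tends to erode the others. This package implements a
multivariate alternative: reduce six standardized yield-related traits to a
few principal components, combine the component structure into a single
composite index, select the top-scoring F1 hybrids, and validate the response
in their F2 progeny.

The six traits, in the fixed order every matrix and weight vector in the
package uses (`trait_names()`):

| symbol | column | unit | meaning |
|---|---|---|---|
| X1 | `height_cm` | cm | plant height at initial flowering |
| X2 | `branches` | count | primary branches above the crown |
| X3 | `fhr` | — | fresh weight / dry weight (>= 1 by construction) |
| X4 | `lsr` | — | leaf dry weight / stem dry weight |
| X5 | `mf_pct` | % | compound leaves with >= 4 leaflets, in [0, 100] |
| X6 | `dry_weight_g` | g | dry biomass per plant |

## The model

**Standardization.** Each trait is centered and scaled by the mean and
*sample* SD (n − 1) of a reference population — the population being analysed,
or an explicit reference when scoring one generation on another's scale.
Correlation-matrix PCA is scale-free, so the sample-vs-population SD choice
does not affect coefficients; sample SD is used because it is what standard
statistical software reports.

**PCA.** The 6 × 6 Pearson correlation matrix R is eigendecomposed. With
eigenpairs (λk, ek), loadings are a_jk = e_jk √λk (squared loadings in a
column sum to λk), component coefficients are the unit eigenvector entries
c_jk = a_jk / √λk, and component k explains 100 λk / 6 percent of the
variance. Components with λ > 1 are retained (Kaiser rule; a fixed-K and a
cumulative-variance rule are available — the elbow criterion is left to the
user's judgement on the scree table).

**Index construction.** Trait j's weight combines its coefficients across the
K retained components, weighted by each component's variance share and
normalized by the total retained variance:

w_j = Σk c_jk v_k / Σk v_k,  k = 1…K.

An individual's composite score is Y_i = Σj w_j z_ij on standardized traits.
Because the score is linear, this equals combining the individual's component
scores with the same variance weights — an identity the tests assert to
1e-10.

**Selection.** Scores are ranked descending (ties broken by id, dense ranks).
The threshold rule keeps scores strictly greater than the cutoff; fraction
and count rules absorb boundary ties and report the realized fraction.

**Validation.** The five populations (selected F1, all F1, selected-lineage
F2, non-selected-lineage F2, all F2) are compared per trait with one-way
ANOVA followed by Duncan's multiple range test, and by percent changes
between named population pairs. "All" populations pool their lineages, as in
the underlying trial, so the groups overlap by construction; the letters
describe that design rather than independent samples.

## Duncan's multiple range test

No installed package provides DMRT, so it is implemented here. For a stretch
of p adjacent ordered means the critical range is

R_p = q(1 − α_p, p, df_error) √(MS_error / n_h),  α_p = 1 − (1 − α)^(p−1),

with q the studentized-range quantile (`qtukey`), MS_error and df_error from
the ANOVA, and n_h the harmonic mean group size (the standard device for
unequal groups, flagged in the result). Letters come from the
insert-and-absorb construction on descending means: each starting mean
extends to the farthest mean whose whole span is homogeneous, maximal spans
get letters, and a range inside a non-significant wider range is never
declared significant (Duncan's protection). The implementation is checked
against published table values of the significant studentized ranges (2.95
and 3.10 at α = 0.05, df = 20, p = 2, 3) and against an independent all-pairs
oracle on random data. With two groups the test reduces to the pooled t-test
decision, which is also asserted.

For summary-only input (group means, SDs, n — all a published table offers),
MS_error is pooled from the group SDs with df = Σ(n_i − 1); on balanced raw
data this reproduces the raw-data letters exactly.

## The bundled reference tables

Raw per-plant data from the underlying trial were never published, so the
package bundles its summary surface (`alfalfa_reference()`): the variance
table, the loading matrix, the printed component coefficients and index
weights, the 90 ranked F1 composite scores, per-population trait summaries
with Duncan letters, and the five reported F1 correlations.
`verify_reference_values()` recomputes the derivable quantities from those
tables; all 29 checks pass. Three arithmetic wrinkles surfaced while doing
so, and the package sides with the reproducible value in each case:

* **Variance share of the third component.** The worked weight calculation in
  the source prints 19.937 where the variance table says 16.937; only 16.937
  reproduces the published height weight 0.210. The package uses 16.937.
* **Intermediate rounding.** The published weights follow from the
  *full-precision* chain (loadings ÷ √eigenvalue, then the variance-weighted
  sum). Rounding coefficients to 3 decimals first would give 0.211 for plant
  height instead of the published 0.210. Coefficients recomputed from the
  printed (3-decimal) loadings and eigenvalues match the printed formulas
  within one unit in the third decimal, the best achievable given rounded
  inputs; 16 of 18 match exactly.
* **Non-derivable percentages.** The reported −8.2% FHR change and the
  −7.2%/−14.1% yield declines cannot be reproduced from any pair of published
  means (the means give −7.93% for FHR and −10.87%/−9.28% for the declines).
  These metrics are computed and reported from means, never asserted at the
  published values, and the decline baselines are configurable
  (`yield_decline()`).

Two labelling conflicts in the source tables are handled by noting them: the
all-F1 dry-weight dispersion appears once as 47.46 and once as 19.46 (the
means agree; both values are stored with their source), and one table calls
its dispersion column standard errors while showing the same numbers labelled
SD elsewhere — they are treated as SDs.

## The synthetic-data generator

`generate_population()` draws multivariate-normal traits with target means,
SDs and correlations (via `MASS::mvrnorm`), then clamps to the biological
bounds. Clamping rates are attached to the result, and a spec placing more
than 5% of its mass beyond a bound warns, since clamping then biases the
realized moments. Gaussians with post-hoc bounds were chosen over bounded
families (beta, lognormal) because the trial reports only means ± SD — there
is nothing to fit a shape to. The paternal line's multifoliolate frequency is
declared constant at 0 rather than simulated near the bound. User correlation
matrices that are not positive semidefinite are repaired by eigenvalue
clipping and re-normalization, with the largest entry change reported; only 5
of the 15 trait pairs have published correlations, and the remainder default
to 0 because no other information exists.

`generate_scenario()` wires the two-generation design: parents and F1 are
drawn, the F1 is scored with a composite index (built on the fly from its own
PCA unless a model is supplied), the top 31.1% (28/90) are selected, and each
F2 lineage is drawn with means shifted by the univariate breeder's equation
Δμ_j = h²_j S_j, where S_j is that lineage's selection differential against
the full F1 mean. Correlated response enters through the F1 correlation
structure at selection time; a full multivariate G-matrix response is out of
scope because no genetic covariance data exist for these materials.

**Default conditions.** Parental and F1 means/SDs are the published ones. The
trial never states parental sample sizes; the default uses n = 45 per line, a
typical single-season evaluation plot. The two F2 lineages default to 45 + 45
plants: every "all F2" mean in the published comparison equals the midpoint
of its two lineage means (e.g. dry weight (143.69 + 112.80)/2 = 128.245 ≈
128.24), which pins equal lineage sizes summing to the stated 90.

**Heritabilities.** True h² values for these materials are unknown. The
defaults (`default_h2()`) are calibration artifacts computed from the
published realized response, (F2_sel − F1_all)/(F1_sel − F1_all) per trait,
clamped to [0, 1]: 0.47 (height), 0.08 (branches), 0.53 (dry weight), and 1
for FHR, LSR and multifoliolate frequency, whose observed responses exceed
their selection differentials (transgressive behaviour a univariate additive
model cannot produce — the generator honestly under-reproduces the +74.78%
multifoliolate gain). Under these defaults the generator's expected
dry-weight selection differential (≈ 37.6 g across seeds) matches the trial's
(36.9 g), and the mean selected-F2 dry weight across seeds lands within 1% of
the published 143.69 g; the test suite asserts the cross-seed mean within
±10%.

**What passing tests do and do not show.** The generator emulates first and
second moments, the published correlation pairs, truncation selection and an
additive per-trait response. It does not emulate non-normal trait shapes,
dominance or epistasis, genotype-by-environment interaction, measurement
error structure, or the across-season yield decline of a real stand — so
pipeline results on synthetic data validate the statistical machinery, not
agronomic claims about real populations.

## Numerical choices

* **Eigenvector orientation.** Signs are arbitrary; each component is
  oriented so its largest-absolute-loading trait is positive. Comparisons
  with published loadings are made up to per-component sign.
* **Near-zero eigenvalues** (rank-deficient input) are clamped at 1e-10 to 0
  and flagged; the decomposition still returns.
* **Composite-score scale.** Scores default to z-score inputs, matching the
  published index formula. The published ranked scores span −15.83 to 35.40 —
  far outside what unit-variance inputs can produce with weights summing
  below 1, and consistent with unscaled mean-deviations dominated by dry
  weight. A `scoring_scale = "centered"` mode reproduces that convention; no
  test or verification depends on the ranked list's magnitudes, only on its
  published values as a given input (28 of the 90 exceed 1).
* **Threshold semantics** are strictly greater-than ("scores > 1"); boundary
  ties under fraction/count rules are absorbed and logged.
* **Display rounding.** Human-readable outputs round to the published
  precision (3 decimals for coefficients/weights, 2 for scores and
  percentages; p-values to 3 decimals with small values shown as "<0.001");
  machine-readable outputs keep full precision.
* **Degenerate inputs.** Constant traits abort standardization with the trait
  named; in correlation reports they yield flagged NA rows instead of an
  error. Both-constant t-tests return t = 0, p = 1 (equal means) or p = 0.
  The clamp-warning threshold uses the spec's tail mass, not the realized
  sample fraction, so warnings do not flicker with sampling noise.

## Problem sizes

The test suite runs the decomposition oracles at n up to 20 000, Monte-Carlo
moment recovery at n = 10 000, and the replicate sanity checks (type-I, power,
calibration) at 25–100 replicates of the 90-plant design — sizes chosen so the
Monte-Carlo error is a small fraction of each asserted tolerance. The whole
suite completes in well under a minute on one core.

## Known limitations

* The index is exactly the variance-weighted PCA construction — no
  economic-weight (Smith–Hazel) or BLUP machinery.
* The response model is univariate-additive per trait; correlated response is
  captured only through selection-time correlations.
* Duncan's test assumes the ANOVA variance structure; no nonparametric
  fallback beyond Spearman correlations is provided.
* The comparison stage inherits the trial's overlapping population design;
  its letters should be read as descriptive of that design.
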