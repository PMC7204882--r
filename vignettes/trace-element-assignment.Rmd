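---
title: "Geographic assignment from trace-element fingerprints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geographic assignment from trace-element fingerprints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traceassign)
```

## The problem

Migratory pest birds (the motivating case is the European starling in an
agricultural valley system) are trapped in fall at vineyards, orchards,
dairies and feedlots, and managers want to know where those birds hatched.
Bone mineral (hydroxyapatite) substitutes dietary cations into its matrix
while a bird is growing and then turns over very slowly, so the
trace-element composition of the leg bone of a juvenile records the
geochemistry of its natal area. `traceassign` implements the complete
statistical workflow around that idea:

1. build a *fingerprint library* from summer-caught juveniles of known
   origin,
2. test that sites differ at all (MANOVA),
3. reduce the element panel and construct canonical discriminant functions
   (stepwise discriminant analysis),
4. assign fall-caught *problem birds* to their most plausible source site,
   flagging birds too far from every source as immigrant/unassigned, and
5. corroborate the spatial structure with hierarchical clustering scored by
   multiscale-bootstrap support values.

A synthetic-data generator reproduces the statistical structure the
analysis assumes, so every step of the workflow can be validated against
known ground truth.

## Preprocessing: calcium ratios and z-scores

Bone is a mixture of collagen (which binds metals poorly) and apatite
(which binds them readily), and the mineral fraction varies between birds
and with age. Dividing every element concentration by the bird's calcium
concentration cancels this mineral-to-collagen variability, which is why
concentrations are expressed per unit calcium rather than per unit mass
(`normalize_to_calcium()`). With the default 21-element panel this yields
20 dimensionless ratios per bird. Ratios are then z-scored per element
(`fit_scaler()` / `apply_scaler()`, n−1 denominator) so that abundant
elements cannot dominate the multivariate analyses.

The training (juvenile library) statistics define the reference frame: by
default problem birds are standardized with the *library* scaler, not with
statistics pooled over all birds — the library is the yardstick the unknown
birds are measured against. A `pooled` mode exists for the one analysis
where juveniles and problem birds enter symmetrically, the all-birds
clustering view (`run_config(scaler_mode = "pooled")`). Canonical
discriminant analysis is invariant to per-element affine rescaling, so this
choice affects only the distance-based clustering, not the classifier.

Missing or below-detection values are rejected outright; substituting half
a detection limit is a lab-side decision we deliberately keep out of the
statistical defaults.

## MANOVA

`manova_wilks()` computes Wilks' Λ = det(W)/det(W + B) from the within- and
between-site scatter matrices and refers it to an F distribution through
Rao's approximation: with m = N − 1 − (p + k)/2 and
t = sqrt((p²(k−1)² − 4)/(p² + (k−1)² − 5)) (t = 1 when the denominator is
non-positive),

  df1 = p(k − 1),  df2 = m·t − df1/2 + 1,
  F = ((1 − Λ^{1/t})/Λ^{1/t}) · (df2/df1).

For the study design (p = 20 elements, k = 10 sites, N = 105 juveniles)
this gives df = 180, 645.230. Bartlett's χ² form is also reported because
the discriminant module reuses it for residual-function tests. Pillai,
Hotelling–Lawley and Roy statistics are intentionally not offered.

## Stepwise canonical discriminant analysis

`stepwise_select()` is the classical forward-with-removal loop, gated by
partial F. With q variables in the model, a candidate's F-to-enter is

  F = ((N − k − q)/(k − 1)) · (Λ_q/Λ_{q+1} − 1),

and the symmetric F-to-remove uses the ratio without the variable. Among
candidates clearing `f_enter` (default 3.84; removal at 2.71 — the
long-standing defaults of the major commercial implementation), the
entrant either minimizes the model Wilks' Λ (`criterion = "wilks"`;
equivalent to maximizing F-to-enter) or maximizes the smallest pairwise
Mahalanobis D² between site centroids
(`criterion = "mahalanobis_closest_pair"`, the default — it targets exactly
the failure mode that matters here, confusable neighbouring sites).
Numerically collinear candidates are skipped with a warning; a repeated
selection state stops the loop. Ties are broken by larger partial F, then
panel order, so output is deterministic.

`fit_canonical()` eigen-decomposes W⁻¹B (via the Cholesky-whitened
symmetric form) and scales coefficients so each canonical score has pooled
within-group variance exactly 1 and grand mean 0; the sign convention makes
the largest-magnitude coefficient positive. It reports eigenvalues λᵢ,
canonical correlations rc = sqrt(λ/(1+λ)), variance shares λᵢ/Σλ, residual
Wilks tests after removing leading functions, per-site centroids, and
standardized coefficients. Functions with λ above
`retention_threshold` (default 1, with at least one always retained) are
used downstream; in unit-within-variance canonical space, squared Euclidean
distance to a centroid *is* Mahalanobis D², so `classify()` is a
nearest-centroid rule with equal priors (trapping effort, not abundance,
determined sample sizes). Ties go to the first site in library order.

`loo_crossvalidate()` refits the canonical functions for each held-out bird
with the element selection held fixed — matching the conventional
"cross-validation" of discriminant analysis; `reselect = TRUE` gives full
nested re-selection when an unbiased error estimate matters more than
comparability. Press's Q = (N − nK)²/(N(K−1)) on the cross-validated count
tests whether classification beats chance.

## Assigning problem birds and flagging immigrants

A problem bird's retained canonical scores f_j are divided by each site
centroid's values, ρ_{s,j} = f_j / centroid_{s,j}: a bird sitting exactly
on a site's centroid scores 1 on every function for that site. Closeness to
site s is the Euclidean distance of ρ_{s,·} from the all-ones vector — the
minimal reading of "how closely the normalized value approximates the
centroid". Centroid components below 10⁻⁹ in magnitude would make ratios
explode; those cells are dropped from that site's closeness (with a
warning) rather than letting one near-zero coordinate dominate. A plain
canonical-space Mahalanobis closeness (`method = "mahalanobis"`) is also
provided; the two agree on the chosen site for birds near a centroid.

A bird is *immigrant/unassigned* when its smallest D² to any centroid
exceeds a threshold τ. The textbook choice τ = χ²₁₋α(r) (r = retained
functions) is exact only for a bird drawn from a known model; with a
library estimated from 105 birds the out-of-sample distances are inflated
by estimation error in the coefficients, centroids and pooled covariance,
and we measured 10–35% false flags at α = 0.05 even for ideal
multivariate-normal data. The package therefore calibrates τ by default on
the leave-one-out min-D² distribution of the training birds themselves
(stored by `build_library()`): τ is its (1−α) empirical quantile, so a new
bird genuinely from a library site is flagged with probability ≈ α by
exchangeability, whatever the within-site distribution. The χ² cut remains
available (`tau`, or automatically for libraries fitted without
calibration data), and the in-sample self-assignment rate under it is ≈ α
for normal data, which is the regime it is valid for.

`summarize_by_context()` tabulates assigned origins per capture context
(vineyards/orchards vs dairies/feedlots) with an optional roll-up onto
user-supplied regional groupings (e.g. north/central/south); the groupings
are configuration data, not code.

## Clustering with multiscale-bootstrap support

`agglomerate()` performs Lance–Williams agglomeration (through the standard
`stats::hclust` engine) with `ward.D` — Ward update coefficients applied to
*unsquared* dissimilarities, the classic convention — plus `ward.D2` and
UPGMA `average`; distances are Euclidean or 1 − Pearson correlation between
bird profiles. `cut_dendrogram()` cuts by height or by cluster count; any
height rule of thumb is data-scale specific, so no cut height is
hard-coded anywhere.

`multiscale_bootstrap()` scores every internal node. For each scale r in
{0.5, …, 1.4} it draws B resamples of round(r·p) feature columns with
replacement (columns, not rows — the convention of multiscale bootstrap for
clustering), reclusters, and records the fraction of replicates containing
each original clade, BP(r). With ψ(r) = Φ⁻¹(1 − BP(r)) fitted by weighted
least squares (binomial delta-method weights) to ψ(r) ≈ √r·v + c/√r, the
approximately unbiased support is AU = 1 − Φ(v − c); BP is reported at
r = 1. BP values of 0 or 1 are clamped to 1/(2B) and 1 − 1/(2B) before the
probit transform; clades never observed get AU = 0 with a saturation flag,
and clades with fewer than two usable scales are flagged undefined. With a
single unit scale and c constrained to 0 the estimate reduces to BP, a
useful sanity anchor. B defaults to 1000 per scale (tests use 100–200 for
speed); AU ≥ 0.95 is the conventional bar for strong support.

## The synthetic-data generator

`synth_config()` encodes the study conditions: 10 named sites with juvenile
sample sizes {20, 10, 10, 9, 9, 18, 10, 8, 6, 5} (105 birds), a 20-element
ratio panel, and 118 fall problem birds. Element ratios are generated
lognormally — concentrations are positive and right-skewed, and the
pipeline z-scores the *ratios* exactly as it would for real data. Site mean
vectors in log-ratio space are the sum of (a) a smooth geographic gradient:
every element loads on two "valley axis" coordinates whose spacing mirrors
realistic inter-site road distances, so nearby sites get similar
fingerprints and misclassification concentrates among neighbours; and (b) a
site-idiosyncratic geochemical component with per-element relevance
weights, so some elements carry little signal and variable selection has
real work to do. These structural constants are fixed (independent of the
run seed); all sampling randomness derives from the single config seed.

Chosen-once defaults, with reasoning:

* `sigma = 0.5` log-units within-site SD (≈ 50% biological CV, typical for
  trace elements in tissue).
* `delta = 1.5` separation multiplier; the axis is normalized so the
  farthest site pair is 10·δ within-site SDs apart, giving nearest-pair
  separations well under 1 SD. At the default this produces leave-one-out
  accuracy near 80% with 10–13 elements selected and ~5 retained functions —
  the separability regime of real bone-chemistry libraries — while keeping
  neighbouring sites confusable. `delta = 0` removes all signal (accuracy
  collapses to chance) and accuracy grows monotonically with `delta`.
* immigrants (default 40% of problem birds) displace *every* element's log
  mean by 10 within-site SDs with random signs: a bird from a
  geochemically distinct region differs in all elements at once, and only
  this reading keeps an immigrant far from every centroid in whatever
  element subset the stepwise selection retains. A displacement along a
  random 20-dimensional unit vector would mostly vanish under projection
  onto the selected-element canonical space and is not what "displaced from
  every library site" means operationally.
* calcium is lognormal around 250 000 µg/g (CV 10%), the order of magnitude
  of Ca in bone mineral.

What the generator does *not* emulate: instrument noise and drift,
detection limits, inter-annual variation in site signatures, age-dependent
turnover in adults, and non-lognormal heavy tails. Passing tests on
synthetic data therefore demonstrate the statistical machinery — selection,
calibration, recovery of planted structure — not field-level performance of
any particular element panel.

## Numerical choices and degenerate inputs

* Wilks' Λ by determinants of scatter submatrices; canonical decomposition
  through Cholesky whitening of W (singular W raises a rank error rather
  than silently pseudo-inverting).
* Candidate variables that make the within scatter numerically singular are
  skipped during stepwise selection with a logged warning.
* A site reduced to one bird during leave-one-out stays in the model with
  its single row (a warning notes the bird can never self-assign).
* Ties: panel order for variables, library order for sites; exact ties
  only, no tolerance fuzzing. All randomized procedures take explicit
  seeds and are bit-reproducible under them.
* Model files are single JSON documents, matrices row-major with label
  arrays, written at full double precision (round trips agree to ~1e-15
  relative error).

## Known limitations

* Under the χ² threshold (non-calibrated libraries) the false-flag rate for
  out-of-sample birds exceeds α, increasingly so with skewed ratios, small
  per-site n and many retained functions; the calibrated default exists
  precisely because of this.
* The stepwise path is greedy; it matches the exhaustive best subset of
  equal size in the tested regimes but carries no optimality guarantee in
  general, and the reported Press's Q inherits the usual selection
  optimism when selection is not re-run inside cross-validation.
* Assignment is a hard nearest-centroid call; no posterior probabilities or
  continuous origin surfaces are produced.
* Multiscale bootstrap support is computed for the clades of the observed
  tree only, and feature resampling assumes exchangeable elements.

## Problem sizes used in the test suite

The packaged tests validate the workflow at the study scale (105 library
birds, 118 problem birds, 20 elements, 10 sites) for the pipeline checks,
with 1000 null simulations for the MANOVA size check, bootstrap B of
100–200 for support-value tests, and 4–6-leaf instances for the exact
agglomeration oracles; the full acceptance script runs in well under a
minute on one CPU.
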