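# traceassign

Geographic assignment of migratory birds to natal origin from bone
trace-element fingerprints.

## The problem

Juvenile birds grow their bone mineral where they hatch, and the apatite
matrix substitutes dietary cations that reflect local geochemistry; bone
then turns over slowly, preserving that natal signature. Given a
*fingerprint library* of summer-caught juveniles of known origin, the
origin of fall-caught "problem birds" trapped at vineyards, orchards,
dairies and feedlots can be inferred — or the birds exposed as immigrants
from unsampled areas. The package is aimed at movement ecologists and pest
managers working with multi-site trace-element (or comparable multivariate
chemical) panels.

## What it computes

With element concentrations normalized to calcium and z-scored, the
workflow is:

* **MANOVA** across sites on the 20-ratio matrix: Wilks'
  Λ = det(W)/det(W+B) with Rao's F approximation
  (F = ((1−Λ^{1/t})/Λ^{1/t})·(df2/df1), df1 = p(k−1),
  df2 = m·t − df1/2 + 1).
* **Stepwise canonical discriminant analysis**: partial-F gated
  forward/backward selection (F-to-enter 3.84, F-to-remove 2.71; entrant
  optimizes Wilks' Λ or the smallest between-centroid Mahalanobis D²),
  then the eigen-decomposition of W⁻¹B scaled to unit pooled within-group
  score variance. Functions with eigenvalue > 1 are retained; rc =
  √(λ/(1+λ)).
* **Leave-one-out cross-validation** with the confusion matrix, per-site
  and overall accuracy, and Press's Q = (N − nK)²/(N(K−1)).
* **Origin assignment**: per-site centroid ratios ρ_{s,j} =
  f_j/centroid_{s,j} (a bird at a centroid scores exactly 1 everywhere);
  nearest site by closeness of ρ to the all-ones vector (or canonical-space
  D²), with birds whose min D² exceeds a leave-one-out-calibrated
  threshold flagged **immigrant/unassigned**.
* **Hierarchical clustering** (ward.D/ward.D2/average on Euclidean or
  correlation distances) with **multiscale-bootstrap** AU/BP support per
  clade: BP(r) from feature resampling at scales r, ψ(r) = Φ⁻¹(1−BP(r))
  fitted as √r·v + c/√r, AU = 1 − Φ(v−c).
* A **synthetic generator** reproducing the study design (10 sites,
  n = {20,10,10,9,9,18,10,8,6,5}, 118 problem birds, valley-axis site
  structure, injected immigrants) for ground-truth validation.

## Worked example

```r
library(traceassign)

cfg       <- synth_config(seed = 42)      # study-design defaults
juveniles <- generate_library(cfg)        # 105 juveniles, 10 sites
problems  <- generate_problem_birds(cfg)  # 118 fall birds, 40% immigrants

built <- build_library(juveniles)         # ratios -> z -> stepwise -> canonical
print(built$manova)
#> One-way MANOVA (Wilks): lambda = 4.812e-05, F = 8.378, df = 180, 645.230, p <2e-16
#>   N = 105 birds, p = 20 variables, k = 10 groups
print(built$library)
#> Fingerprint library: 10 sites, N = 105 birds
#>   elements: Cr, Sc, Ag, K, Co, Zn, Mn, Se, Cd, Sr
#>   canonical functions: 9 (5 retained, eigenvalue > 1)
#>   eigenvalues: 5.532, 4.756, 2.356, 1.916, 1.447, 0.931, 0.257, 0.099, 0.041
#>   variance shares: 31.9%, 27.4%, 13.6%, 11.1%, 8.3%, 5.4%, 1.5%, 0.6%, 0.2%
print(built$cv)
#> Leave-one-out classification: 81.9% correct (86/105, 10 sites)
#>   Press's Q = 603.20 (p <2e-16); resubstitution 91.4%
#>   per-site %: Kelowna 85, Hullcar 90, Salmon Arm 100, Armstrong 78, Mara 78,
#>               Vernon 89, Oliver 40, Osoyoos 88, Penticton 83, Keremeos 80

zp  <- apply_scaler(built$library$scaler, normalize_to_calcium(problems))
asg <- assign_origin(built$library, zp, method = "mahalanobis")
summ <- summarize_by_context(asg, problems$context)
summ$vineyard_orchard$table[1:4, ]
#>                 source  n       pct
#> 1 immigrant_unassigned 30 45.454545
#> 2            Penticton  7 10.606061
#> 3               Vernon  7 10.606061
#> 4                 Mara  6  9.090909
```

Reading the output: the MANOVA df pair (180, 645.230) is fixed by the
design (20 elements, 10 sites, 105 birds); the tiny Λ and large F say site
fingerprints differ strongly. Stepwise selection kept 10 of 20 elements;
five canonical functions have eigenvalue > 1 and carry ~92% of the
among-site variance. Cross-validated accuracy is 81.9% against a 10% chance
level (Press's Q rejects chance at any conventional level); the weakest
site (Oliver, 40%) loses birds mostly to its nearest neighbour, as real
libraries do. In the assignment summary, 45% of the vineyard/orchard birds
were too far from every library centroid (the generator injected ~40%
immigrants plus an α = 5% false-flag allowance) and the rest are spread
over source sites.

There is also a thin command-line front end
(`inst/exec/traceassign-cli.R`) with `simulate`, `preprocess`, `manova`,
`train`, `crossvalidate`, `assign`, `cluster` and `report` subcommands
writing CSV/JSON/Newick artifacts.

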