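---
title: "Maximum-entropy niche modelling with entniche: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy niche modelling with entniche: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entniche)
```

## The model

`entniche` fits a presence-background species distribution model: given
occurrence locations of a species and a stack of gridded environmental
predictors, it estimates a suitability surface without true absences by
contrasting the presences against a random sample of landscape cells (the
*background*). The estimator is the constrained maximum-entropy (Gibbs)
density

$$q_\lambda(x) = \exp(\lambda \cdot f(x))/Z_\lambda,$$

normalized over the background, with coefficients minimizing the
L1-penalized negative mean presence log-likelihood

$$f(\lambda) = -\tfrac1m\textstyle\sum_i \lambda\cdot f(x_i) + \log Z_\lambda
  + \sum_j \beta_j |\lambda_j|.$$

This objective is convex; the penalty both prevents overfitting with
small samples and performs feature selection (most coefficients stay
exactly zero). Two assumptions matter in practice: the occurrences are
treated as an unbiased sample of where the species lives (no survey-bias
correction is implemented), and the background is treated as
representative of available environments (it is drawn uniformly from the
jointly valid cells, up to 10,000 of them, seeded). By default the
presences are appended to the normalization background, which keeps the
density well defined even when presences occupy environments absent from
the background draw.

Reported suitability is the **cloglog** transform
$1 - \exp(-e^{H}\,q_\lambda(x))$ where $H$ is the entropy of the fitted
background distribution. It is strictly increasing in the raw density,
lies in $(0,1)$, and equals $1 - e^{-1} \approx 0.632$ everywhere for the
uniform (fully shrunk) model — a closed form the tests assert.

## Features and their penalties

Predictors are expanded into bounded $[0,1]$ features: linear and
quadratic terms of min-max-scaled values, pairwise products, threshold
indicators $1(x > k)$, and forward/reverse hinges. Knots are placed at
evenly spaced interior quantiles of the pooled presence + background
values, 50 per variable by default for threshold and for each hinge
direction; quantile capping keeps the design matrix bounded regardless of
sample size. Scaling bounds come from the pooled samples (the estimation
domain), not the full raster. At projection time inputs outside the
training bounds are **clamped** to them by default, so projected features
remain in $[0,1]$ on novel climates.

The per-feature penalty is
$\beta_j = \mathrm{RM}\cdot\beta_{\mathrm{class}}(m)\cdot s_j/\sqrt m$:
$s_j$ is the feature's standard deviation over presences (floored at its
presence range over $\sqrt m$, with a fallback of $1/\sqrt m$ — the full
feature scale — for a feature constant over presences, so every penalty
stays positive), and $\beta_{\mathrm{class}}$ interpolates sample-size
tables: linear/quadratic/product $(0,1.0)\,(10,1.0)\,(30,0.2)\,(100,0.05)$,
threshold $(10,2.0)\,(100,1.0)$, hinge constant $0.5$, clamped outside the
tabulated range. The regularization multiplier RM scales all penalties
globally; the package default is RM 1 with linear + hinge + threshold
features, the complexity level this model family typically selects by
AICc at $m \approx 125$ presences. Both are explicit arguments of
`maxent()`.

## The solver

Cyclic coordinate descent with soft-thresholding: each coordinate takes a
damped Newton step on the smooth part of the objective (gradient
$-\bar f_j + E_q[f_j]$, curvature $\mathrm{Var}_q(f_j)$) followed by the
L1 proximal map, then a step-halving backtrack on the *true* objective,
so every accepted update strictly decreases it and the regularized gain
trace $\ln N - f(\lambda)$ is nondecreasing — an invariant the tests
assert. Log-sum-exp evaluations subtract the running maximum before
exponentiation. Convergence is declared when a full sweep improves the
objective by less than `tol` (default $10^{-4}$) or after `max_iter`
(default 5000) sweeps. On tiny instances (≤3 features, ≤20 background
rows) the solver objective agrees with a dense grid-search minimum to
well under $10^{-3}$; across nested RM values total coefficient mass
$\sum_j|\lambda_j|$ is nonincreasing.

## Tuning, evaluation, importance

`tune_grid()` evaluates all 31 nonempty feature-class subsets × RM 0.5–5
in steps of 0.5 (310 candidates): per candidate, k-fold cross-validated
validation AUC, train–validation AUC difference and the 10-percentile
omission rate (threshold = the $\lceil 0.1\,m_{\mathrm{train}}\rceil$-th
lowest training presence score, count-based; omission counts validation
presences strictly below it), plus AICc of the full-data fit with the raw
density renormalized over *every* valid landscape cell and $K$ = nonzero
coefficients. The correction term is undefined at $K \ge n-1$, reported
as `NA`. Selection takes `delta_AICc = 0`; ties break by parsimony
(smallest $K$), then smaller RM, then lexicographic feature string.

Evaluation metrics: rank AUC over all presence–background pairs (ties
count half); TSS = sensitivity + specificity − 1 at the maxSSS threshold,
with background as the *pseudo-absence* class (true absences do not
exist in this design — the specificity is a pseudo-specificity) and
presences at the threshold counted positive; and the continuous Boyce
index, the Spearman correlation between the presence-to-landscape
frequency ratio P/E and the window centre over 101 moving windows of
width 10% of the landscape score range. Windows with no landscape mass
are dropped; constant scores, fewer than three usable windows or a
constant P/E return 0 with a degeneracy flag. Two properties of this
estimator are worth knowing: it is only *approximately* invariant under
monotone score rescaling (ranking is, window membership is not), and its
null distribution for an uninformative model is wide (sd ≈ 0.35 with the
default overlapping windows) though centred at zero — single CBI values
near ±0.3 from small samples carry little signal.

Percent contribution credits each accepted solver update's gain increase
to the updated feature's source variable (products split 50/50), floors
negative totals at zero and normalizes to 100. It is **path-dependent**:
reproducible conditional on the coordinate-descent update path.
`permutation_importance()` (shuffle a column, measure the training-AUC
drop, normalize) is the path-independent cross-check. Jackknife gains fit
with-only and without-each-variable models; response curves sweep one
variable across its training range with the others held at their
presence means (marginal mode) or refit on the variable alone
(univariate mode).

## Projection, classification, areas

`project_map()` applies the frozen feature transform (with clamping) and
cloglog to every valid cell; `ensemble_mean()` averages aligned
projections across climate-model ensembles, nodata dominating.
`classify_suitability()` cuts a suitability map into five classes at
breaks $(t, 2t, 3t, 4t)$ — multiples of the maxSSS threshold, which
requires $t < 0.25$ — or at user-supplied breaks. Reported break values
use decimal half-up rounding (`round_half_up()`): base R's half-to-even
rounding turns 0.1945 into 0.194, whereas conventional reporting prints
0.195. Cell areas use exact spherical geometry with the authalic Earth
radius 6371.0088 km, so per-class areas sum to the land total by
construction and a whole-sphere grid closes to $4\pi R^2$. Change tables
support both denominator conventions — percentage of the present area
(default) or of the future area — recorded in the output metadata, and
report an infinity marker rather than a number when a class appears from
nothing.

## The synthetic landscape

`gen_climate_stack()` emulates a WorldClim-style stack: 19 layers named
`bio1..bio19`, each a random latitudinal/longitudinal gradient plus
moving-average-smoothed white noise (kernel 5 cells, configurable),
rescaled into role-appropriate ranges — temperature-like layers ≈ 10–35,
precipitation-like ≈ 0–2500, the seasonality layer ≈ 20–200. A
correlation plan rebuilds chosen layers as affine mixes of a source layer
and a residualized independent field, so the realized sample correlation
equals the target exactly; the default plan creates five collinear pairs
(|r| 0.85–0.95), the structure that makes the |r| ≥ 0.8 screen
meaningful. True suitability is a product of plateau-Gaussian responses —
flat at 1 inside the optimum range, Gaussian falloff outside — with
default optima 22–28 (bio1), 300–1000 (bio12) and 70–160 (bio15) and
falloff widths 2, 150 and 20 respectively, roughly a third of each
plateau's half-width: wide enough that suitability varies smoothly over
most of the landscape, narrow enough that the optima are identifiable
from 125 points. Occurrences draw cells without replacement with
probability proportional to suitability, then place a point uniformly
inside the cell.

What it does *not* emulate: survey bias, spatial sampling clumped along
roads or fields, anisotropic climate gradients, GCM physics or real
CMIP6 anomaly patterns (scenarios are affine deltas), and non-climate
drivers. Passing recovery tests therefore demonstrates that the
estimator recovers a known climate-driven truth from unbiased samples —
not that any real-world prediction is unbiased.

## The recovery experiment

The end-to-end validation generates the default world, screens the stack
at |r| ≥ 0.8 with the three drivers placed at the head of the priority
list — the analog of the expert's "biologically important" choice that
this screening design models explicitly, and necessary because a
|r| = 0.95 clone can edge out its true driver by a sliver of univariate
gain, moving named credit to an equivalent surrogate — then fits at
default settings. Across seeds the fitted cloglog surface attains
landscape Spearman correlation > 0.9 with the truth, the three drivers
carry 80–93% of percent contribution with the top two contributors
always drivers, and the temperature response curve peaks inside the
plateau ± one falloff width. The precipitation-seasonality driver
legitimately ranks mid-pack on its own: its plateau covers most of its
layer's range, so it constrains the density weakly. A "sharply
separable" variant narrows the plateaus (24–26, 500–800, 100–140 with
widths 0.5, 30, 5), making suitable habitat rare (≈1–7% of cells); there
the training AUC exceeds 0.97 — AUC against background is bounded above
by ties between presences and suitable background, so only a
low-prevalence truth can support near-1 values.

## Degenerate inputs and numerical conventions

Constant predictors are excluded from features with a warning and
recorded with correlation 0 in the screening matrix. Grids use half-open
cell membership (a point on a shared edge belongs to the cell whose
lower/left edge it touches); occurrences are deduplicated to one per
cell by default (standard hygiene, configurable off). ESRI ASCII rasters
round-trip bit-for-bit in header integers and to better than $10^{-10}$
in values; the `xllcenter` dialect converts by subtracting half a cell.
Nonzero coefficients are counted at $|\lambda_j| > 10^{-12}$; solver
backtracking accepts at objective decrease below $10^{-12}$.

Test and validation problem sizes were chosen to exercise every path at
interactive scale: an 80×80-cell default world (6400 cells — below the
10,000-background cap, so the background is the full landscape plus
presences), 60×60 for the regularization sweep, and 25–40-cell grids in
module tests. The acceptance script re-runs the full pipeline in under a
minute on one CPU.

## Known limitations

No sample-bias grids, categorical predictors, logistic/cumulative output
formats, spatial-block cross-validation partitions, or map
reprojection. Percent contribution is meaningful only relative to the
solver path; prefer permutation importance when comparing across
software. AICc here follows the landscape-normalization convention; other
implementations differ in the normalization domain, so absolute AICc
values are not comparable across packages, though rankings usually are.
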