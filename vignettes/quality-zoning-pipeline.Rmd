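---
title: "From niche models to quality zoning: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From niche models to quality zoning: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmaniche)
```

pharmaniche chains three analyses that in medicinal-plant research are
usually run in three separate tools: a maximum-entropy species
distribution model (SDM) over environmental raster layers, chemometric
processing of chromatographic fingerprints of the harvested material, and
a regression-driven fuzzy overlay that turns both into a spatial quality
regionalization. This vignette explains the models behind each stage,
the parameters that matter, the numerical decisions taken where the
methodology is conventionally left implicit, and what the synthetic-data
module does and does not establish about real data.

## The maximum-entropy model

Presence-only SDMs ask: given points where a species was recorded and a
raster stack of environmental covariates, what is the relative
probability that a random cell hosts the species? The maximum-entropy
answer models the occurrence distribution over environment space as the
Gibbs form

$$q(x) \propto \exp\big(\lambda \cdot f(x)\big)$$

over the fitting sample (presences plus a uniform background sample of
valid cells), where $f$ is a feature expansion of the covariates. The
coefficients $\lambda$ minimize the L1-penalized negative mean
log-likelihood of the presences,

$$-\tfrac1{n}\sum_{i \in \text{pres}} \lambda\cdot f(x_i) + \log Z(\lambda)
  + \sum_j \beta_j |\lambda_j|,$$

which is the dual of entropy maximization subject to relaxed
feature-expectation constraints. We report the *gain*
$\log N - \text{(objective)}$, zero for the uniform model.

**Feature classes.** Continuous covariates contribute a linear and a
quadratic feature; categorical covariates one indicator per observed
category. Hinge, product and threshold features are deliberately
omitted: the fit stays convex and fast, per-feature gain attribution
stays interpretable, and smooth response surfaces (which is what both the
synthetic truths and climatological covariates look like) are captured
by the quadratic terms. This is a documented deviation from the Java
MaxEnt tool, whose default feature set depends on sample size. All
features are min-max scaled to $[0,1]$ on the training sample and the
scaling is stored in the model.

**Regularization.** No single published default exists for this feature
set, so the package states one: $\beta_j = m \cdot
\mathrm{sd}_{\text{bg}}(f_j) / \sqrt{n_{\text{pres}}}$ with multiplier
$m = 1$. The $1/\sqrt{n}$ scaling is the standard maxent-style
sample-size dependence: more presences, less shrinkage.

**Optimizer.** Cyclic coordinate descent with a proximal Newton step and
soft-thresholding per feature, with backtracking so the penalized gain is
non-decreasing, stopping when a full cycle improves the gain by less than
`tol` (default `1e-5`) or after `max_iter` cycles (default `1e4`; in
practice a few dozen cycles suffice). Coordinate-wise fitting is chosen
over quasi-Newton precisely because it yields the per-feature gain
credits that *percent contribution* needs.

**Outputs.** Raw output is $q(x)$ normalized over the fitting sample;
cloglog output $1 - \exp(-e^{H} q)$ (the modern default, where $H$ is the
entropy of the fitted distribution) and logistic output
$q e^H / (1 + q e^H)$ are monotone transforms of it into $[0,1]$. AUC is
computed in Mann-Whitney form — the fraction of presence/background score
pairs ranked correctly, ties half-counted — with the conventional verbal
grades: below 0.6 the model fails, below 0.7 poor, 0.7–0.9 good, above
0.9 excellent.

**Diagnostics.** Percent contribution credits each accepted coordinate
update's gain improvement to the updated feature's source layer and
normalizes to 100. Permutation importance shuffles one layer at a time
across presences and background and reports the normalized mean AUC
drop. The jackknife refits with only, and without, each layer. One
subtlety is deliberate: jackknife gains are reported on the
*regularized* scale. On the unpenalized scale a submodel refit can score
above the shrunk full model, which would make "without-layer gain never
exceeds the full gain" false; on the penalized scale the bound holds by
construction, because every submodel is the full problem with some
coefficients pinned at zero. Note the bound is resolved only to the
optimizer tolerance — comparisons at `1e-6` need `tol` of `1e-8` or
tighter.

**Replicates and splits.** The fitting protocol splits presences 75/25
(train/test). The underlying report states both "25% testing" and "70%
training"; 75/25 is the consistent reading and is the package default.
`fit_replicates()` repeats split + background sampling + fit (default 10
times) and averages the cloglog maps cell-wise.

## Variable selection

Selection proceeds in three stages, mirroring common SDM practice:

1. **Iterative zero-contribution dropping** — refit, drop every layer
   whose percent contribution falls below $\varepsilon$ (default 0.05%,
   rather than exactly zero, to absorb floating-point credit), repeat
   until stable. The candidate set shrinks monotonically, so the loop
   terminates.
2. **Pearson pruning** — among continuous survivors, process pairs with
   $|r| > 0.8$ in decreasing $|r|$ order and drop the smaller
   contributor of each (exact contribution ties broken by name, making
   the procedure deterministic and independent of column order).
   Correlations are computed at presence points by default — the common
   choice and the one matching extracted-value tables — with the option
   to use background or all cells instead.
3. **Consensus main factors** — the intersection of the top-$k$ layers
   (default $k = 10$) under percent contribution, permutation importance
   and jackknife with-only gain, reported with their cumulative percent
   contribution.

"Common ecological factors" is not a formally defined notion in the
field; the top-$k$ intersection is this package's explicit
interpretation, and $k$ is exposed.

One behavior worth knowing: on spatially autocorrelated covariates, the
L1 penalty may legitimately assign zero contribution to a weakly
weighted layer that is partially collinear with a strong one. Stage 1
will then drop a layer that did enter the generating truth. This is a
property of penalized likelihood, not a defect; the recovery tests are
therefore phrased over strongly weighted truths.

## Suitability zoning

Suitability maps are classified into unsuitable / low / moderate / high
zones. The default breaks are the fixed thresholds 0.1 / 0.3 / 0.6 with
half-open intervals $[0,0.1), [0.1,0.3), [0.3,0.6), [0.6,1]$ — the
bracket convention is stated because interval notation in applied
reports is ambiguous at the endpoints. A Fisher-Jenks natural-breaks
classifier (`jenks_breaks()`) is available as the data-driven
alternative: an exact dynamic program over the sorted values minimizing
within-class SSE, verified in the tests against exhaustive partition
enumeration.

Zonal areas use latitude-corrected cell areas on degree grids — a cell
at latitude $\varphi$ covers $(c \cdot 111.32\ \mathrm{km})^2
\cos\varphi$ for cell size $c$ in degrees — and flat $c^2$ areas on
metre grids. Scenario comparison reports per-class area change rates
$100(\text{future}-\text{current})/\text{current}$ computed from exact
(unrounded) areas, plus the full class-transition matrix.

## Fingerprint chemometrics

Chromatograms enter as (time, signal) series. Peaks are local maxima
above a height threshold with sufficient topographic prominence; bounds
sit at the enclosing prominence minima and areas are trapezoidal
integrals over a linear local baseline. Retention-time correction fits a
monotone piecewise-linear warp through peaks matched to a few anchor
times (multi-point correction); common peaks are greedy retention-time
clusters (width ≤ `rt_window`, default 0.3 min) containing exactly one
peak from *every* sample — the standard 100%-presence convention for
herbal fingerprints. The reference ("control") fingerprint is the
column-wise median of the common-peak areas (median rather than mean for
robustness to a single aberrant sample; a flag switches). Similarity is
the included-angle cosine of area vectors — the default measure of the
similarity-evaluation software used in this field — so it is invariant
to per-sample dilution. Marker peaks come from a correlation-matrix PCA:
retain components with eigenvalue ≥ 1, compute loadings as eigenvectors
scaled by the root eigenvalue, and select peaks with $|$loading$| > 0.8$
on any retained component. "Contribution degree" is read as the absolute
loading; squared-loading or score-coefficient readings would select
slightly different sets, and both thresholds are parameters.

## Linking chemistry to environment

Group differences between suitability classes use the Mann-Whitney U
test: statistic $\min(U, n_1 n_2 - U)$ with ties half-weighted, exact
two-sided p from the full null distribution (computed by a counting
recursion) when $n_1 n_2 \le 400$ and the data are untied, otherwise a
normal approximation with tie and continuity correction. Two-sided
tests, no multiplicity correction — matching the source methodology.

Regressions of functional factors on the main ecological factors use
SPSS-style stepwise OLS: forward entry of the smallest-p candidate below
`p_enter` (0.05), backward removal above `p_remove` (0.10) after every
entry, to a fixed point, final model refit by OLS. Perfectly collinear
candidates never enter. Plain stepwise does *not* control the familywise
entry rate: with $p$ idle candidates the chance of at least one spurious
entry is about $1 - 0.95^p$, so with ~10 candidates roughly 40% of
pure-noise runs select something, and exact support recovery on strong
signals fails by one extra term at a similar rate. The tests assert
recovery bounds consistent with that arithmetic. The 22 published
equations over the 10 main factors ship as a JSON fixture
(`read_regression_models()`), evaluated by exact linear algebra.

Spearman correlation between ecological and functional factors uses
average-rank transforms with t-approximation p values, flagged at 0.05
and 0.01; ecological factors are grouped by average-linkage hierarchical
clustering on the distance $1 - |\rho|$, cut at $k = 3$.

## Quality overlay

Each regression model is evaluated cell-wise into a concentration
raster, min-max normalized to $[0,1]$ ("a linear function"), and the
normalized rasters are fuzzily overlaid together with the (already
$[0,1]$) suitability map: AND = min, OR = max, SUM $= 1-\prod(1-v_i)$,
PRODUCT $=\prod v_i$, GAMMA $=$ SUM$^\gamma\,$PRODUCT$^{1-\gamma}$.
The default is GAMMA with $\gamma = 0.9$ — the common GIS practice where
the report says only "fuzzy superposition". Cell-wise, PRODUCT ≤ AND ≤
every input ≤ OR ≤ SUM, and GAMMA lies between PRODUCT and SUM. Cells in
the unsuitable class are masked from the final map. Three factor subsets
are predefined: medicinal (marker peaks + index components + effective
compound groups), edible (nutritional components and elements),
comprehensive (all). Two stated conventions: every factor is treated as
"higher is better" (invertible per factor), normalization happens over
all valid cells *before* masking (a flag switches), and suitability
enters the overlay as one more membership layer rather than as a
multiplier.

## The synthetic-data module

No occurrence set, raster stack or chromatogram accompanies the source
study, so the package ships generators with recorded ground truth; every
downstream stage is tested as a recovery problem.

* `gen_env_stack()` — continuous layers are Gaussian random fields
  (white noise smoothed by a separable Gaussian kernel at a length scale
  in cells, reflected at edges), standardized to mean 0, sd 1. Collinear
  pairs are planted as $y = 0.95x + 0.1\varepsilon$, giving empirical
  $|r| \approx 0.99$. Categorical layers are Voronoi patches around
  random seeds. Default scene: 100×100 cells, 12 continuous + 1
  categorical layer, 2 collinear pairs, length scale 8.
* `gen_occurrences()` — cells sampled without replacement with
  probability $\propto \exp(\sum w_l x_l)$, one point uniform inside
  each cell. The Gibbs form means the maxent fit is *correctly
  specified*; misspecification stress is out of scope. Default weights:
  three informative layers (+2, −1.5, +1), the magnitudes a field
  ecologist would call strong but not degenerate effects.
* `gen_chromatograms()` — 20 Gaussian peaks on a 0–50 min gradient with
  log-normal per-sample area multipliers (areas stay positive and
  right-skewed, as chromatographic areas are), Gaussian retention-time
  jitter (default sd 0.05 min) and white baseline noise.
* `gen_functional_factor_table()` — sparse linear models of the layer
  values at each sample's cell plus Gaussian noise, coefficients
  recorded for recovery tests.

Every generator is a pure function of its parameters and seed.

**What passing these tests shows — and does not.** The synthetic scenes
establish internal correctness: the optimizer finds the generating
structure when the model is correctly specified, the selection pipeline
removes planted collinearity, the fingerprint chain recovers planted
peaks under realistic jitter, fuzzy overlays obey their algebra. They do
not establish that the method is well-specified for real vegetation
data: real suitability surfaces are not log-linear in the covariates,
real chromatograms have baseline drift, co-eluting shoulders and missing
peaks, real sampling is spatially biased, and real quality–environment
links are not sparse linear models. Headline figures of the source study
that depend on its undeposited field data (its AUCs, its zonal areas,
its similarity table, its PCA variance) are therefore not reproduction
targets; the packaged worked values are restricted to quantities fully
determined by printed tables.

**Problem sizes.** The shipped tests and the acceptance script run the
default 100×100 scene with 200 presences, a full-background fit
(≈10,200 fitting points, ~27 features), 10 replicate fits, 10-seed
recovery loops and 6-sample × 2,501-point chromatograms — sizes chosen
so the complete pipeline executes in well under a minute on one core
while leaving each estimate comfortably away from its acceptance bound.

## Known limitations

* No reprojection, resampling or GeoTIFF/shapefile I/O: all layers must
  arrive on one shared grid as ESRI ASCII (the source workflow resampled
  externally, and the target resolution it used is unstated).
* Linear + quadratic + indicator features only; no clamping or
  extrapolation flags outside the training range (response curves and
  predictions extrapolate the quadratic).
* Percent contribution is path-dependent (credited along the coordinate
  descent trajectory), as in the reference software; permutation
  importance and the jackknife are the path-free complements.
* The fingerprint module assumes baseline-resolved Gaussian-ish peaks;
  heavily fused peak clusters will defeat the prominence-based bounds.
* Stepwise regression inherits the classical caveats (biased
  coefficients post-selection, no familywise control); it is provided
  because it is the field's convention, with full-OLS evaluation of
  published equations as the fixture path.
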