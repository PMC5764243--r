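---
title: "Methods: multiscale ordination and variogram analysis of benthic communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale ordination and variogram analysis of benthic communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(benthicMSO)
```

## The problem

A grab-sample survey of the seafloor observes the benthic community at a set
of stations separated by, typically, hundreds of metres. Community variation
at scales *below* that sampling interval is invisible to the survey, yet it
still contributes to the total variance that any regression of community
structure on environmental variables is judged against. This package
quantifies that unresolvable fraction (the variogram *nugget*), checks
whether the variables a survey ordinarily collects account for the spatial
structure it *can* see, and re-expresses explained variance relative to only
the resolvable variation.

## The model

### Hellinger scale

All community variances are computed on Hellinger-transformed abundances,
`x_ia = sqrt(y_ia / y_+a)`. Each sample becomes a unit vector in the squared
sense, so Euclidean distances between samples are Hellinger distances:
composition is compared, dominant taxa are damped, and double zeros carry no
weight. The transform is undefined for an empty sample, so stations with a
zero count total are excluded (with a warning) rather than imputed;
species observed nowhere are dropped on load.

### Empirical multivariate variogram

For station pairs whose separation falls in distance class `h`,

$$\gamma(h) = \sum_{i=1}^{s} \frac{1}{2 n_h}
  \sum_{(a,b)\,:\,d_{ab} \approx h} (x_{ia} - x_{ib})^2 .$$

Two exact identities anchor the implementation and are asserted in the test
suite: summing over *all* pairs gives the total sample variance `s²`
(pair-weighted mean of per-class values, tolerance 1e-10), and inserting an
ordinary-least-squares decomposition `x = x^fit + x^res` gives, per class,

$$\gamma(h) = \gamma_{fit}(h) + \gamma_{res}(h) + \gamma_{cross}(h)$$

to machine precision, with the cross term twice the per-class covariance of
fitted and residual differences.

Distance classes are half-open `[lower, upper)` (final class closed at the
cutoff), a determinism choice — the edge convention is otherwise arbitrary.
Class positions are reported as arithmetic midpoints of the edges. Only
classes below half the maximum extent `h_max/2` are used: beyond that
distance, central stations can no longer contribute pairs and the estimates
become biased. The class width defaults to the smallest of 0.25, 0.50,
0.75 km that yields at most 12 classes under the cutoff, aiming at roughly
ten `γ(h)` values with, ideally, at least 30 pairs each (classes below 30
pairs trigger a warning, not an error). The per-class standard error is the
standard deviation over pairs of the per-pair species-summed halved squared
difference, divided by `sqrt(n_h)`; pairs sharing a station are correlated,
so this "naive" standard error is treated as approximate wherever it enters
a test (see the stationarity check below).

### Parametric variogram models

Five families are fitted: exponential, Gaussian, spherical, piecewise
linear, and logistic, each with nugget `c0`, partial sill `c1` and rate
parameter `a` (km, except the logistic where `a` multiplies `h²` and has
km⁻² semantics). All are nondecreasing with `γ(0) = c0`; the spherical and
piecewise-linear families clamp at the sill `c0 + c1` for `h ≥ a`.

Fitting minimizes the pair-count-weighted residual sum of squares subject to
`c0, c1 ≥ 0` and `a > 0` (negative variances are meaningless, so the bounds
are enforced by bounded optimization rather than left to chance). Because
such fits are sensitive to starting values, a small multi-start grid is
used — `c0` at 25/50 % of the first class value, `c1` starting at
`max(γ) − c0`, `a` at 25/50/100 % of the cutoff (inverse-squared cutoff for
the logistic) — followed by a quasi-Newton polish; the best result is kept.
Model choice uses AICc, `n ln(RSS/n) + 2K + 2K(K+1)/(n−K−1)`, with `n` the
number of usable classes and `K = 4` for every family (three coefficients
plus the error variance, the usual least-squares convention). Ties are
broken by a fixed canonical family order so the selection cannot depend on
the order families are tried. No standard errors are reported for variogram
parameters: the pair reuse in the variogram violates the independence
assumptions of bootstrap or cross-validation error estimates.

The *derived range* is `a` for the clamped families and the smallest `h`
with `γ(h) = 0.95 (c0 + c1)` for the asymptotic ones (closed form for the
exponential and Gaussian; bracketing bisection to 1e-6 km for the logistic).
Note this definition depends on the nugget: with a large nugget, 95 % of the
*total* sill is reached early. For recovery studies against a generating
spatial covariance, `correlationRange()` gives the nugget-invariant
analogue (95 % of the partial sill above the nugget), which is the quantity
commensurable with the practical range of a latent field.

### RDA, forward selection, province merging

Redundancy analysis is ordinary least squares of each centered Hellinger
species profile on the centered design (equivalently, with intercept),
followed by eigenanalysis of the fitted covariance; the canonical eigenvalue
sum over `s²` is the explained fraction. Continuous covariates are
z-standardized before selection so conditional gains are comparable;
provinces enter as binary 1/0 indicators, one per province, with no
reference level dropped — collinearity at the full set is resolved by
dropping aliased columns (with a warning) via a pivoted QR.

Forward selection adds, at each step, the candidate with the largest
conditional gain in explained variance (ties broken by name order for
determinism), records each step's AICc (`K` = design columns + intercept +
error variance), and finally truncates the greedy path at its AICc minimum;
the empty model is a legitimate outcome. The province *merge search* is a
deterministic greedy agglomeration: starting from singleton groups, the pair
of groups whose merger least decreases explained variance is merged,
each configuration's province-only RDA AICc is evaluated, and the
minimum-AICc configuration along the path is returned. For three provinces
the greedy path provably contains the exhaustive-search optimum (all pair
merges share the same `K`, so the least-variance-decrease pair is also the
min-AICc pair); the test suite verifies equality with full partition
enumeration at `k = 3`. Provinces with fewer than two stations are first
absorbed into the group with the nearest composition centroid.

### MSO diagnostics

Three diagnostics interrogate the decomposition:

* **Scale dependence.** A Bonferroni-corrected envelope
  `γ(h) ± z_{1−α/(2m)} · se(γ(h))` is drawn around the empirical variogram;
  a class whose `γ_fit + γ_res` leaves the envelope has a cross term
  distinguishable from zero, i.e. the biotic–environmental relationship
  changes with scale. `m` counts classes with at least 5 pairs. Normal
  critical values with the per-class standard error are used; this is the
  natural construction of a point confidence interval here.

* **Residual autocorrelation.** Per class, a Mantel statistic correlates the
  squared residual distances with the binary pair-membership of the class,
  with two-sided permutation p-values at the Bonferroni level `α/m`.
  Least-squares residuals are *not* exchangeable: the projection makes
  residual distances systematically larger for pairs in the same design
  cell, and naive row/column permutation of the residual distance matrix was
  observed (in this package's own null simulations) to reject far above the
  nominal level under province designs. The null distribution is therefore
  generated Freedman–Lane style: residual rows are permuted and re-projected
  through the model's residual maker before distances are recomputed, so
  every permuted replicate carries the same fitted-model structure as the
  observed data. Sidedness is a design choice; two-sided is used because
  both directions of departure are interpretable.

* **Residual stationarity.** A weighted least-squares line is fitted to
  `γ_res(h)` over the upper half of the classes — "did the residual
  variogram reach a sill and stay there" — using inverse squared per-class
  standard errors as weights (fixed-effect meta-regression). Because those
  standard errors ignore the correlation between pairs sharing a station,
  the slope variance is inflated by the standard multiplicative
  overdispersion factor `max(1, X²/(k−2))`. Stationarity holds when the
  slope's 95 % interval covers zero. A t-interval from the handful of
  upper-half points alone was found to have essentially no power against a
  clearly rising residual variogram; the meta-regression form restores power
  while the overdispersion factor protects the null.

### Within/between-province partition

The same pair-sum machinery is applied to two "distance" classes — pairs
within a province and pairs between provinces — plus an overall row over all
pairs (so the pair-weighted combination of the two classes reproduces the
overall values exactly). Subtracting the site-level nugget `c0` of the
selected variogram model from `γ_res` gives the adjusted explained fraction
`γ_fit / (γ_fit + (γ_res − c0))` per class and overall. A single site-level
nugget is used in both classes: per-province variograms would require on the
order of 35 stations per province, beyond the designs emulated here. Where
the nugget exceeds the residual, the negative adjusted residual is reported
verbatim and the fraction flagged at 1 — never silently capped — since a
negative remainder is a real, interpretable outcome of subtracting an
independently estimated small-scale variance from a regression residual.

## The synthetic-site generator

`simulateSite()` emulates the study design the pipeline targets: a
rectangular domain of a few km² tiled by a Voronoi mosaic of contiguous
provinces; stations placed stratified-randomly with at least three per
province where feasible; species composition differing between provinces;
within-province spatially autocorrelated variation with a finite range; and
uncorrelated small-scale variation that surfaces as a Hellinger-scale
nugget.

Defaults (all overridable in `syntheticConfig()`): 60 stations on a
4 × 2 km domain, 6 provinces, 30 taxa, mean total count 300 per grab,
latent exponential field with practical range 0.8 km and sill 0.5, province
effect 1.0, nugget-fraction target 0.45. These sit inside the regimes the
pipeline is meant for: a few dozen to a hundred stations over 3–16 km²,
5–10 provinces, nugget fractions of roughly a third to a half of the total
variance, and ranges well below the maximum extent.

Construction notes:

* The latent field uses an exponential covariance
  `spatialSill · exp(−3h / spatialRangeKm)`, simulated by Cholesky
  factorization (designs up to a few hundred stations). The range parameter
  is the *practical* (95 %) range so it is commensurable with the 95 %-rule
  ranges reported for fitted models.
* Counts default to a multinomial draw conditioned on a Poisson total,
  reflecting fixed-area grab sampling; a Poisson-per-species alternative is
  available. Count sampling itself contributes small-scale variance, so the
  realized nugget fraction has a count-noise floor.
* White noise is injected on the latent (pre-count) scale. The Hellinger
  transform distorts variances nonlinearly and no closed form links the
  latent noise sd to the realized nugget fraction, so `calibrateNugget()`
  calibrates it empirically: the realized median scaled nugget (through the
  full variogram-fit-and-select path) is measured on a fixed grid of
  candidate sds, the monotone response is isotonized, and the sd meeting the
  target is interpolated and verified. A sequential bisection was tried
  first and found fragile under Monte-Carlo noise. If the count-noise floor
  alone exceeds the target, the best achievable value is returned with a
  flag.
* Depth is a smooth monotone large-scale gradient plus measurement noise;
  percent sand/mud derive from province means plus noise. A nonzero
  `depthEffect` makes species load on the depth gradient — the hook for
  misspecification studies in which a spatially structured driver is
  withheld from the candidate set.
* Same seed and config give byte-identical output; the generator restores
  the caller's RNG state.

What the generator does *not* emulate — and hence what passing tests do not
establish about field data: taxon abundance distributions with realistic
rarity structure (log-normal-like latent means are used, not fitted rank
curves), gear selectivity and subsampling error, temporally repeated
sampling, province shapes derived from real geomorphology (Voronoi cells are
convex), anisotropy, and measurement error in coordinates. Diagnostic
calibration rates and recovery errors established under the generator are
statements about the procedure under these idealized conditions.

## Validation studies and problem sizes

The test suite fixes its own seeds and uses deliberately modest problem
sizes chosen to characterize behaviour well while keeping the suite quick to
run:

* *Nugget/range recovery*: 50 sites of 200 stations on a 4 × 4 km domain,
  nugget target 0.45, practical range 0.8 km, province effect zero — a pure
  stationary field, so the generator's range is the estimand; with a
  province mosaic present, the community variogram's range legitimately
  reflects province patch size rather than the latent field range. The
  white-noise sd is calibrated once and shared across the 50 seeds. Recovery
  is summarized by the median absolute error of the scaled nugget and the
  median relative error of the correlation range.
* *Diagnostic calibration*: 200 null replicates (50 stations, 5 provinces,
  province-only truth and design, white noise only) at 199 permutations per
  Mantel test; family-wise Mantel rejections and scale-dependence flags are
  compared against the nominal 0.05.
* *Misspecification power*: 50 replicates with a depth-driven community and
  the depth gradient withheld from the design; the stationarity flag is
  expected to trip in at least 80 %.
* *Selection behaviour*: 100 replicates of 3 true log-linear drivers among
  7 noise candidates (40 stations, 20 taxa); and greedy-vs-exhaustive merge
  search at `k = 3`.

## Known limitations

* The variogram-parameter sampling distributions are unknown; no standard
  errors accompany `c0`, `c1`, `a`, and AICc comparisons between families
  rest on an approximate normal-residual assumption for weighted
  least-squares fits.
* The per-class standard error (and everything downstream of it) treats
  pairs as independent; the overdispersion correction in the stationarity
  check mitigates but does not remove this.
* The Freedman–Lane Mantel test is asymptotically, not exactly, calibrated.
* The merge search is exact at `k = 3` but greedy beyond; it can miss
  non-nested optimal partitions for many provinces.
* Geographic coordinates must be projected planar km; no lat/lon support.
* `n` beyond a few hundred stations will make the dense-matrix steps
  (Cholesky simulation, pairwise distance work, permutations) slow.
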