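# benthicMSO

Spatial-scale analysis of multivariate benthic community data: how much
community variation lies *below* the sampling interval of a grab-sample
survey, and how well do environmental covariates and sonar-derived habitat
provinces explain the variation the survey can actually resolve?

The package is aimed at benthic ecologists and biostatisticians working with
site-by-species abundance tables, projected station coordinates, per-station
environmental measurements and a categorical habitat ("acoustic province")
label per station. It implements the full pipeline as tested, reusable
functions, plus a synthetic-site generator so that every stage can be
exercised and validated without field data.

## What it computes

**Empirical multivariate variogram.** With Hellinger-transformed abundances
`x_ia` (square root of the within-sample relative abundance of species *i*
in sample *a*), the community semivariance at geographic distance class *h*
is

    γ(h) = Σ_i  1/(2 n_h)  Σ_{(a,b): d_ab ≈ h} (x_ia − x_ib)²

summed over species, where `n_h` counts the station pairs in the class.
Summed over *all* pairs instead of a class, the same expression equals the
total sample variance `s²`. Only classes below half the maximum extent
(`h_max/2`) are used.

**Variogram models and the nugget.** Five parametric families —
exponential, Gaussian, spherical, piecewise linear, logistic — are fitted by
pair-count-weighted least squares and compared by AICc. Each fit yields the
nugget `c0` (community variance below the sampling interval), the sill
`c0 + c1`, and the range (where the model reaches the sill, or 95 % of it
for the asymptotic families). `c0/s²` is the fraction of community variance
the survey cannot resolve.

**RDA and multiscale ordination (MSO).** Hellinger abundances are regressed
on environmental covariates and binary province indicators (redundancy
analysis) with AICc-guided forward selection and a greedy
province-merging search. Inserting the fitted and residual matrices into the
variogram decomposes it per class:

    γ(h) = γ_fit(h) + γ_res(h) + γ_cross(h)

with three diagnostics: a Bonferroni-corrected envelope around `γ(h)` (scale
dependence of the biotic–environmental relationship), per-class Mantel tests
of residual spatial autocorrelation (Freedman–Lane permutations), and a
residual-stationarity check (weighted slope of `γ_res` over the larger
distance classes).

**Within/between-province partition.** Replacing geographic classes with two
"distance" classes — pairs within the same province versus pairs in
different provinces — and subtracting the nugget from `γ_res` gives
explained-variance fractions for only that part of the variation within the
observational scale of the survey.

## Worked example

Simulate a site with a known nugget fraction, then run the full pipeline:

```r
library(benthicMSO)

cfg <- syntheticConfig(seed = 42, nStations = 80, domainKm = c(4, 2),
                       nProvinces = 6, nuggetFracTarget = 0.45)
cal <- calibrateNugget(cfg)       # tune the latent white noise to the target
cfg$whiteNoiseSd <- cal$whiteNoiseSd

report <- runSite(simConfig = cfg, seed = 42, nPerm = 199)
report
```

```
Site analysis report (seed 42 )
  80 stations, 30 taxa, s2 = 0.3236
  variogram: linear model, c0 = 0.136, sill = 0.376, range = 1.456 km
  scaled nugget = 0.422, scaled range = 0.360
  selected variables: province_C, province_F, province_E, province_B, province_A
  explained fraction = 0.535; nugget-adjusted overall = 0.925
  diagnostics: scale-dependent = FALSE; stationarity ok = TRUE; Mantel sig = FALSE
```

Reading the output: the piecewise-linear variogram model won the AICc
comparison; its nugget is 42 % of the total Hellinger variance (`s² =
0.324`), i.e. nearly half the community variation occurs below the sampling
interval — close to the 0.45 the generator was calibrated to. Forward
selection retained five province indicators; the nonspatial RDA explains
53.5 % of the total variance, and after the unresolvable small-scale
variance is subtracted from the residual, 92.5 % of the *resolvable*
variance. The diagnostics find no scale dependence, stationary residuals and
no residual spatial autocorrelation, so the selected variables account for
the spatial structure the survey can see.

Per-family fits are in `fitTable(report$fits)`, the per-class MSO table in
`as.data.frame(report$mso)` (plot it with `plot(report$mso)`), the
within/between-province partition in `as.data.frame(report$partition)`, and
`writeSiteReport(report, "out/")` serializes everything (CSV + JSON).

Field data are read with `readSite("community.csv", "stations.csv")`
(stations file columns: `id, x_km, y_km, province`, then covariates).

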