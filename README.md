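# famap

Maps of household welfare — who has enough to eat, and from which
livelihood activities — are usually drawn from aggregated data or expert
masks, hiding the enormous household-to-household variation underneath.
`famap` implements a stepwise regression-kriging procedure that works at
the household level instead: it turns geo-referenced survey records into
country-scale prediction maps, with 95% prediction intervals, for the
**food availability** indicator and the **contribution shares** of crops,
livestock and off-farm income. It is aimed at quantitative researchers in
food security, agricultural economics and spatial epidemiology who have
LSMS-style survey tables and covariate rasters.

## The method in brief

For each household, food availability is

```
FA = (E_consumed + E_income) / (365 × n_hh-mae)   [kcal cap⁻¹ d⁻¹]
```

— energy from unsold own production plus all income converted to
staple-food energy, per male adult equivalent per day. Contribution
shares of each activity are proportions in [0, 1] with point masses at
both ends.

The mapping pipeline per indicator:

1. **Regression.** log-FA ~ covariates by OLS; shares by multiple
   zero-and-one-inflated beta regression (MIBR), a four-parameter model
   (μ, σ, ν, τ) with `P0 = ν/(1+ν+τ)`, `P1 = τ/(1+ν+τ)`,
   `α = μ(1−σ²)/σ²`, `β = (1−μ)(1−σ²)/σ²` and
   `E(y) = (τ+μ)/(1+ν+τ)`. Covariates pass a univariate p < 0.1 screen
   and a VIF < 10 collinearity filter, then stepwise AIC selection per
   distribution parameter.
2. **Residual geostatistics.** Regression residuals are normal-score
   transformed (100 intervals, 0.5%/99.5% truncation), their spatial
   structure is fitted by method-of-moments variograms (spherical and
   exponential candidates, pair-count/distance² weights), summarised by
   the nugget-sill ratio (≤ 0.7 flags spatial autocorrelation), verified
   by leave-one-out cross-validation, and interpolated by ordinary
   kriging (regression kriging for FA).
3. **Composition.** Prediction surface + back-transformed residual
   median, with `μ ± 1.96σ` bounds; proportion maps are clamped to
   [0, 1] after addition.

A synthetic-data module generates covariate rasters, clustered and
privacy-displaced household locations, and survey records that invert the
FA computation exactly — so the whole pipeline is testable by parameter
recovery against known truth.

## Worked example

```r
library(famap)
scene <- generateScene(seed = 11)                 # 1000 households, 48×48 grid
report <- runPipeline(scene$households, scene$covariates,
                      indicators = c("FA", "banana"), seed = 11)
print(report)
```

```
retained 1000 of 1000 households (0 excluded)
Stepwise mapping run report
  indicator family   n fit_stat_ev fit_stat_evhr aic_ev     shape nugget  sill
1        FA    MLR 981       0.117         0.119   1979 spherical  0.288 0.434
2    banana   MIBR 981       0.512         0.513    678    matern  0.633 1.011
  range_km nugget_sill_ratio spatial_fraction structured loo_msse failure
1     60.0             0.663             33.7       TRUE     1.02    <NA>
2     47.7             0.626             37.4       TRUE     1.04    <NA>
spatially structured indicators: 2
```

Reading the report: FA has a weak environmental trend (R² = 0.12, barely
improved by household resources, R² = 0.12), while the rain-driven
`banana` share is well explained (pseudo-R² = 0.51). The residual
variograms show that 33–37% of the residual variance is spatially
structured (`spatial_fraction`), both indicators fall under the ≤ 0.7
nugget-sill rule (`structured`), and the leave-one-out mean standardised
squared errors near 1 say the variogram models are well calibrated. The
composed maps live in `report$details$banana$maps` (`median`, `lower`,
`upper` grids) and can be written with `writeReport(report, "out/")`,
which also emits the report as CSV/JSON and the maps as ESRI ASCII grids:

```r
m <- report$details$banana$variogram
m
#> VariogramModel: matern (kappa = 0.5), nugget 0.633, sill 1.011,
#>                 range 47.68 km (ratio 0.63)
round(spatialFraction(m), 1)
#> [1] 37.4
```

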