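---
title: "Mapping household food availability by inflated-beta regression kriging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping household food availability by inflated-beta regression kriging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National household surveys record, for a few thousand geo-referenced
households, what a family grows, sells and earns. Decision makers, however,
need *maps*: spatially continuous estimates of welfare indicators, with
honest uncertainty. `famap` implements a stepwise procedure that turns
point-level survey data into such maps for the household **food
availability** indicator (FA) and for the **contribution shares** of
livelihood activities (crops, livestock, off-farm income) to FA.

The procedure has three steps:

1. **Regression.** Each indicator is regressed on spatially continuous
   environmental covariates (rainfall, growing period, soil carbon stock,
   population density, market access, ...). Log-FA is approximately normal
   and uses ordinary least squares (MLR). Contribution shares are
   proportions with many exact zeros and ones and use a multiple
   zero-and-one-inflated beta regression (MIBR).
2. **Residual geostatistics.** The regression does not capture all spatial
   structure. Residuals are normal-score transformed, their spatial
   autocorrelation is summarised in a variogram model, and they are
   interpolated by kriging.
3. **Composition.** The regression prediction surface and the
   back-transformed kriged residual surface are added; 95% prediction
   intervals come from the kriging standard deviation. Proportion maps are
   clamped to [0, 1] after the addition.

## The indicator

For each household,

$$\mathrm{FA} = \frac{E_\mathrm{consumed} + E_\mathrm{income}}
                   {365 \times n_\mathrm{hh\text{-}mae}}
  \quad [\mathrm{kcal\ cap^{-1}\ d^{-1}}],$$

where $E_\mathrm{consumed}$ is the annual food energy from own production
that was not sold (produced minus sold quantities, valued at product energy
densities), $E_\mathrm{income}$ converts all income — product sales plus
off-farm income — into energy of the staple food (maize) through the staple
price and energy density, and $n_\mathrm{hh\text{-}mae}$ standardises
household size to *male adult equivalents* using sex- and age-dependent
energy requirements relative to an adult male (2500 kcal cap⁻¹ d⁻¹).

Both configuration tables ship as editable CSVs
(`system.file("extdata", ...)`): the energy/price table carries
placeholder values of realistic magnitude (not copies of any product
database), and the MAE weight table is a documented default
(adult male 1.00, adult female 0.76, descending child bands). Correctness
of the computation is defined relative to the configured tables.
Contribution shares attribute each product's consumed energy *plus* its
sales income (in staple-energy terms) to the product's activity, so
activity shares sum to 1 and product shares sum to their activity share.
Households without land holdings or without any livelihood activity are
excluded, with a logged reason.

## The inflated beta model

A share $y \in [0,1]$ follows a mixed discrete–continuous law with
$P_0 = \nu/(1+\nu+\tau)$ at 0, $P_1 = \tau/(1+\nu+\tau)$ at 1, and a
Beta$(\alpha, \beta)$ density in between, with
$\alpha = \mu(1-\sigma^2)/\sigma^2$, $\beta = (1-\mu)(1-\sigma^2)/\sigma^2$
and expectation $E(y) = (\tau+\mu)/(1+\nu+\tau)$. Each of the four
parameters gets its own linear predictor: logit links for $\mu, \sigma$,
log links for $\nu, \tau$ — the conventional parameterisation for this
distribution. When a response has at most 3 observations equal to 1, the
sample is too small to model one-inflation and the zero-inflated-only
variant (MIBR-0, no $\tau$) is used.

Fitting is maximum likelihood with analytic gradients and a quasi-Newton
(BFGS) optimiser on the joint link-scale coefficient vector; starting
values come from sample moments (empirical endpoint frequencies, interior
mean and variance), standard errors from the observed information. Fit
quality is summarised by the *pseudo-R²*, the squared Pearson correlation
of fitted expectations and observed shares.

### Covariate selection

Model building follows a fixed recipe: (i) *univariate screening* — one
single-covariate model per candidate, keep slopes with $p < 0.1$ (no
multiplicity adjustment; the gate is intentionally liberal). For MIBR the
screening slope sits on the $\mu$ predictor by default (`scope = "any"`
screens all parameters at once); (ii) *collinearity filtering* —
iteratively drop the covariate with the largest variance inflation factor
until all VIF < 10; (iii) *stepwise AIC selection* — forward selection for
MLR (`stats::step`), and for MIBR a cycle over the parameters
$\mu \to \sigma \to \nu \to \tau$ with forward-then-backward moves on each
parameter's predictor, repeated to a fixed point, accepting only
AIC-lowering moves; (iv) *simplification* — the last-added coefficient is
removed when it is not significant, and the simplified model is kept
unless its AIC is worse by more than 10.

The simplification wording in the source procedure is ambiguous in both
the direction of the $p$ rule and the direction of the AIC rule. The
default here is the reading that guards against overfitting (remove when
$p \ge 0.1$; reject the removal when AIC worsens by more than 10); the
literal alternative is available via `simplifyBeinf(pRule = "literal")`.

A nested comparison quantifies what household *resource* covariates (land
area, herd size, household size) add to the environmental model: the EVHR
fit extends the selected EV model with the resource candidates. Prediction
maps always use the EV model, since only environmental covariates are
available wall-to-wall as rasters.

## Residual geostatistics

MIBR residuals $y_\mathrm{observed} - y_\mathrm{predicted}$ are skewed and
bounded, so they are passed through a quantile-based **normal score
transformation** with 100 intervals; the tails beyond the 0.5% and 99.5%
quantiles are truncated to the bounds. The transformation is stored as a
monotone piecewise-linear quantile table and inverted after interpolation
(ranking ties share their common quantile; scores beyond the table clamp
to the boundary values).

The **empirical variogram** uses the method of moments on geodesic (WGS84)
distances with lag boundaries 10, 20, ..., 100, 150, 200 km and a 200 km
cutoff (all overridable). Model fitting minimises the weighted sum of
squared errors with weights $N_j / h_j^2$ (pair count over squared mean
lag distance) over two candidate shapes — spherical and Matérn with
smoothness fixed at $\kappa = 0.5$ (the exponential model) — with
multistart L-BFGS-B under $\mathrm{nugget} \ge 0$. For the exponential
shape the reported range is the distance parameter; the practical range is
about three times it. A fitted range below the shortest observed lag is
unidentifiable and is reported as a pure-nugget model.

The **nugget-sill ratio** (nugget over *total* sill) summarises how much
residual variance is spatially structured: $(1-\mathrm{ratio}) \times 100$
is the spatially structured percentage, and indicators with ratio
$\le 0.7$ are flagged as spatially autocorrelated. Models are verified by
leave-one-out cross-validation (computed exactly from the inverse of the
bordered kriging matrix); the mean standardised squared error should be
near 1 for a calibrated model.

Interpolation is **ordinary kriging** by default (simple kriging with mean
0 is available, since normal-score residuals are near-zero-mean); the full
system is solved once globally below 2000 points, with a 64-nearest-
neighbour scheme above. For FA the trend and residual steps combine into
**regression kriging** of log-FA: the OLS trend (kept as OLS; no
generalised-least-squares refit) plus the kriged OLS residuals, with the
kriging standard deviation as the prediction uncertainty.

## Back-transformation and uncertainty

For FA, the kriged log-scale mean $\mu$ back-transforms to the *median*
$E(Y)=e^{\mu}$ of the lognormal predictive law (deliberately not the
mean), with bounds $e^{\mu \pm 1.96\sigma}$. For shares, the three
normal-score surfaces $\mu$, $\mu \pm 1.96\sigma$ are inverted through the
quantile table and added to the MIBR prediction surface, which is treated
as deterministic — all uncertainty is attributed to lack of fit and
carried by the residual interpolation. Clamping to the valid range happens
*after* the addition, and the cell-wise ordering lower ≤ median ≤ upper is
enforced.

## The synthetic-data generator

No real survey ships with the package; the generator produces scenes whose
ground truth is known exactly, which is what every recovery test runs
against.

* **Covariates** are stationary Gaussian random fields with requested
  marginal mean/sd and practical correlation range, simulated by exact
  Cholesky factorisation below 5000 points (cheap exactness at the scales
  used here) and by a random-Fourier-feature spectral approximation above.
* **Households** cluster in enumeration areas (default 100 EAs × 10
  households on a 4°×4° window at 5 arc minutes — about the retained
  sample size of the national survey this emulates), and the analysis only
  ever sees locations displaced by up to 10 km, as survey publishers do.
* **Shares** follow the inflated-beta law itself: link-scale linear
  predictors of the (sample-centred) covariates plus a shared latent
  Gaussian residual field scaled per parameter. The source procedure has
  no generative model for its data, so this single-shared-field structure
  is a stand-in: the simplest mechanism that produces spatially structured
  residuals of $E(y)$.
* **Survey records** are built by inverting the FA computation: rosters,
  production, sales and incomes are constructed so that recomputing FA and
  the shares reproduces the simulated targets to floating-point accuracy
  (part of each product's share is routed through sales so both energy
  pathways are exercised).
* Two default truths span the contrast of interest: a **signal** truth
  (rain-driven share, strongly spatially structured latent residual:
  nugget 0.1, sill 1.1, practical range 120 km) emulating an
  environment-determined crop, and a **noise** truth (no covariate
  effects, pure-nugget residual) emulating an ubiquitously grown crop.
  With these defaults the pipeline reproduces the qualitative published
  contrast: the driven indicator comes out with pseudo-R² above 0.3 and
  nugget-sill ratio below 0.7, the noise indicator with pseudo-R² near 0
  and ratio near 1. The FA truth is calibrated to a weak trend
  (R² ≈ 0.1–0.2) with a large nugget, matching the published finding that
  FA varies mostly locally.

What the generator does *not* emulate: measurement error in survey
responses, informative sampling, covariate misreporting, non-stationarity,
and anisotropy. Passing recovery tests therefore show the *procedure* is
implemented correctly, not that real surveys meet its assumptions.

## Numerical choices

* Distances are geodesic on the WGS84 ellipsoid; coordinates are never
  projected (ranges are reported in km).
* Grid cells are half-open, $[x, x+\Delta) \times (y-\Delta, y]$, so edge
  points belong to exactly one cell; raster downsampling aggregates by
  block means.
* Coincident published locations are re-jittered by ≤ 50 m (uniform
  distance and bearing, re-drawn on residual collision) because kriging
  needs unique points.
* Link-scale predictors are clamped to ±30 before applying the inverse
  links; the likelihood returns a large finite penalty on non-finite
  values, keeping BFGS inside the domain.
* Kriging systems are solved with a covariance formulation
  ($C(h) = \mathrm{sill} - \gamma(h)$, $C(0)$ includes the nugget);
  near-singular systems are retried once with a jittered diagonal.
* Tiny negative kriging variances from round-off are clamped to zero.
* Soil carbon stock uses the literal layer formula
  $\mathrm{SCARB}_i = BD_i \times \Delta z_i \times SOC_i \times 10^4$
  with the mean over the three standard layers; note that dimensionally
  the product is a mass of carbon per unit area per layer, not the
  concentration unit sometimes attached to it.

## Problem sizes

The shipped tests and the acceptance script run on deliberately modest
problem sizes, chosen as the smallest scales at which every statistical
property is still sharply testable: scenes of 1000 households on a 48×48
raster, regression recovery at n = 2000, variogram recovery at 700–1000
points, leave-one-out calibration at 500 points. All of these are
package-level choices and scale up by changing the corresponding
arguments.

## Known limitations

* The MIBR prediction surface is treated as deterministic; regression
  parameter uncertainty is not propagated (a deliberate model choice of
  the procedure, not an oversight).
* Variogram range estimates from a single realisation are noisy whenever
  the domain spans only a handful of ranges; tests use medians over
  replicates for this reason.
* The pair-count/distance² weighting lets a poorly estimated first lag bin
  pull the fit towards spurious short-range structure in small samples.
* Anisotropy, co-kriging and Bayesian uncertainty are out of scope.
* Raster I/O is plain-text ESRI ASCII grid; the package does not read or
  write GeoTIFF.
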