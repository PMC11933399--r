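---
title: "Methods: district hazard indexing from incomplete well surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: district hazard indexing from incomplete well surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aquahazard` estimates district-level drinking-water hazard from a
national survey of wells in which most records are incomplete, and
converts the result into a population-exposure figure. This vignette
documents the statistical model behind each stage, the default
parameters, and the known limitations.

```{r setup}
library(aquahazard)
```

## The estimation problem

A survey measures up to ten parameters per well — Chloride, Alkalinity,
TDS, Hardness, Sulphate, Nitrate, Nitrite, Phosphate, Fluoride and
Iron — but laboratories rarely run the full panel, so per-parameter
missingness ranges from a few percent to over 70 %. The target quantity
for each district $d$ is a hazard index

$$ H_d = \frac{1}{10} \sum_{i=1}^{10} f_{i,d}, $$

where $f_{i,d}$ is the proportion of the district's area (grid cells) or
wells at which parameter $i$ violates its drinking-water standard.
Violations are strict inequalities against WHO/US EPA limits
(`load_standards("WHO_EPA")`) or Sri Lankan limits (`"SriLanka"`); Iron
is reversed — concentrations *below* 0.3 mg/L count as violations,
reflecting palatability-driven rejection of low-iron groundwater sources
in the source methodology. Districts are classified `low` (< 0.10),
`moderate` ([0.10, 0.20)), `high` ([0.20, 0.30)) and `very_high`
(>= 0.30), and everyone in a district whose index exceeds
`exposure_threshold` (default 0.2) counts as exposed.

Two independent pathways estimate $f_{i,d}$:

1. **Spatial interpolation** of the observed (non-imputed) values of
   each parameter onto a raster, then counting violating cells per
   district (`hazard_by_interpolation()`).
2. **Imputation** of the missing cells of the well table, then counting
   violating wells per district (`hazard_by_imputation()`).

Agreement between the two is itself a diagnostic: they share no
machinery beyond the raw data.

## Random-forest imputation

`rf_impute()` implements iterative chained random-forest imputation on
`ranger`: initialize missing cells with medians, visit variables in
order of increasing missingness, regress each on all others (plus well
depth, yield, groundwater depth, district and climate zone as auxiliary
predictors), and repeat until the normalized sum of squared changes
first increases, returning the previous iterate. Out-of-bag error per
variable is reported as $\sqrt{\mathrm{OOB\ MSE} / \mathrm{Var}(x_{obs})}$.

Accuracy against known truth uses the normalized RMSE over the masked
cells only,

$$ \mathrm{NRMSE} = \sqrt{\frac{\mathrm{mean}\big((x_{true} - \hat x)^2\big)}
{\mathrm{Var}_{pop}(x_{true})}}, $$

with the *population* variance in the denominator, so that predicting
the mean of an MCAR standard-normal column scores exactly 1. Multiple
parameters pool as the square root of the mean of the per-parameter
variance-standardized ratios (`nrmse()`).

## Variograms and ordinary kriging

`fit_variogram()` bins empirical semivariances up to half the maximum
pairwise distance (15 lags) and fits spherical, exponential or Gaussian
models by weighted least squares ($N_h/\gamma^2$ weights). `krige()`
solves the ordinary-kriging system with an unbiasedness constraint; for
grid prediction it uses the dual formulation (a single linear solve
regardless of the number of query cells), computing kriging variances
only on request via per-query solves. Concentrations are kriged in log
space by default (`log_transform = TRUE`), with a **median**
back-transform $\exp(\hat z)$ rather than the lognormal-mean correction
$\exp(\hat z + \sigma^2/2)$: the median transform commutes with the
threshold comparison that drives the hazard index, which is the
package's purpose, at the cost of a low-biased estimate of the mean
concentration. Pass `back_transform = "mean"` for unbiased means.

Nitrate is routed to inverse-distance weighting (power 2, 12
neighbors) instead, following the source methodology's treatment of a
parameter dominated by very local (often sanitation-driven) variation
that a stationary variogram represents poorly.

`loo_standardized_rmse()` gives a fast exact leave-one-out diagnostic
via the augmented-matrix inverse identity ($e_i = \lambda_i / q_i$,
$\sigma_i^2 = 1/q_i$ with $q = \mathrm{diag}(K^{-1})$): values near 1
indicate calibrated kriging variances.

## The weighted arithmetic water quality index

`wawqi_score()` computes $K = 1/\sum_i 1/S_i$, weights $W_i = K/S_i$,
quality ratings $Q_i = 100\,(V_i - V_o)/(S_i - V_o)$ with ideal value
$V_o = 0$, and the score $\sum W_i Q_i / \sum W_i$. A sample exactly at
every standard scores 100; bands are `[0,25)` excellent through
`>= 100` unsuitable. `district_wqi()` averages per-well scores within
districts.

## The synthetic survey generator

National well datasets are typically not redistributable, so the
package ships a generator that emulates one at realistic scale. It is a
*statistical emulation*, not a geological model:

- `generate_districts()`: 25 Voronoi districts from inhibition-sampled
  seeds on a 250 km × 420 km rectangle; climate zones (6 wet, 7
  intermediate, 12 dry) cut from a smooth southwest–northeast dryness
  gradient; 22 million people allocated by zone-weighted density
  (wet : intermediate : dry = 8 : 2.5 : 1) with largest-remainder
  rounding so the total is exact.
- `generate_true_fields()`: per-parameter lognormal fields
  $\mu_{zone} \exp(\sigma Z - \sigma^2/2)$ on a Gaussian random field
  $Z$ with correlation $\exp(-(h/L)^2)$, $L = 40$ km (FFT convolution),
  coefficient of variation 0.8, then *exactly* rescaled so each zone
  mean hits its calibration target — zone contrasts are treated as
  known constants, not estimates. Related parameters (a salinity
  cluster, a nutrient cluster, Fluoride, Iron) share latent fields with
  correlation 0.8.
- `sample_wells()` adds 5 % multiplicative measurement noise;
  `apply_missingness()` deletes completely at random at per-parameter
  rates matching the published survey (4 % for Hardness up to 71 % for
  Phosphate).

Defaults (688 wells, 2 km grid, the rates above) reproduce the scale of
the motivating national survey; all sizes are ordinary arguments.

## Reproducibility

`run_pipeline()` derives one sub-seed per stochastic stage as
`(seed + 99991 * stage) mod (2^31 - 1)` (`derive_seed()`), so a single
master seed fixes the world, the survey, the missingness and the
imputation independently, and writes a manifest of MD5 checksums with
every product.

## Limitations

- **Plug-in exceedance bias.** Counting violating cells on a kriged
  (smoothed) surface is biased wherever a standard sits near the local
  median of the field — smoothing pulls values toward the center, so
  exceedance proportions near 0.5 are attenuated or inflated
  district-by-district. In the default world Nitrite's 1 mg/L limit
  sits almost exactly at the wet-zone median and per-district errors of
  0.2–0.5 in that single parameter's fraction are normal; the
  imputation pathway, which never smooths, does not share this bias.
  An indicator-kriging or conditional-simulation estimator would remove
  it but is out of scope.
- MCAR missingness is assumed throughout; informative missingness
  (e.g., labs skipping tests where contamination is deemed unlikely)
  would bias both pathways.
- The generator's Voronoi districts and smooth climate gradient are
  caricatures of real administrative and climatic geography.
- Trend analysis (`linear_trend()`) is plain OLS on monthly means with
  no autocorrelation correction; its standard errors are optimistic for
  strongly persistent series.
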