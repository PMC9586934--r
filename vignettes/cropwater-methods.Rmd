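---
title: "Methods: gridded crop yield and water productivity estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded crop yield and water productivity estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Crop water productivity (CWP) is the grain yield produced per unit of water
evapotranspired over the growing season, in kg of grain per m^3 of water. It
is a standard indicator of agricultural water-use efficiency, and mapping it
at kilometre scale requires two gridded ingredients: an annual crop-yield
raster and the cumulative growing-window evapotranspiration (ET) raster.
`cropwater` implements the full estimation chain for dryland cereals (maize
and wheat):

1. **Temporal compositing.** Satellite indicator products arrive as 46
   fixed 8-day composites per year (start day-of-year 1, 9, ..., 361) for
   ET (mm/8d), gross primary productivity (GPP, g C/m^2/8d), land-surface
   temperature (Ts) and leaf area index (LAI). Each pixel has its own crop
   phenology window (maize: from the three-leaf stage to maturity; wheat:
   emergence/green-up to maturity). ET, GPP and Ts are summed and LAI is
   averaged over the composites whose start day falls inside the window.
2. **Zonal statistics.** Windowed indicators plus static soil texture
   (clay/sand/silt percent) are averaged over the crop pixels of each county
   and joined with recorded county yields to form the model table.
3. **Yield regression.** A random forest (100 trees, 4 candidate variables
   per split) maps the seven county-level features to yield. 80% of
   county-year records train the model, with the global minimum and maximum
   yield rows forced into training so the forest — an averaging learner that
   cannot extrapolate — sees the full response range. The remaining 20%
   validate it. All 15 non-empty subsets of the four remote-sensing
   indicators are compared (soils always included) and the best model
   generates pixel-level yield rasters.
4. **CWP.** `CWP = yield / (10 * cumET)` converts kg/ha over mm of water to
   kg/m^3 (one mm over one hectare is 10 m^3).
5. **Validation.** RMSE, relative RMSE (percent of the observed mean), mean
   bias error and adjusted R^2 at county and point scale; Global Moran's I of
   county residuals under queen contiguity (near-zero values mean spatially
   random errors); and a multiplicative input-perturbation sensitivity
   analysis.

Alongside the estimation chain sits an eddy-covariance quality-control module
used to benchmark gridded ET products against flux towers: daily records are
screened by their energy-balance closure ratio `ECR = (H + lambdaET)/(Rn - G)`
(days below 0.80 rejected; the comparison is strict, so a day at exactly 0.80
is retained), corrected by the Bowen-ratio rescaling
`lambdaET_cor = lambdaET * (Rn - G)/(H + lambdaET)` (which preserves the
Bowen ratio H/lambdaET while forcing closure), converted to mm/day with a
fixed latent heat of vaporisation of 2.45 MJ/kg, cumulated to the 8-day
grid, and paired with the ET raster pixel at the tower.

# The synthetic world

Real inputs for this chain are multi-gigabyte satellite archives. To make the
pipeline testable end to end, `make_world()` builds a miniature landscape
with *known* generative truth. The default configuration is a 60 x 60 grid of
1-km pixels partitioned into 5 x 5 counties, three years, 15 point-scale
yield sites and two flux towers.

Indicator fields are spatially smooth (a standardized low-order polynomial
trend plus Gaussian-kernel-smoothed noise) modulated by a seasonal bell
centred mid-season, with 3% multiplicative pixel noise per composite. Soil
fractions are three smooth positive fields normalised to sum to 100%. The
phenology window start is drawn smoothly in day-of-year 90-130 and the end in
230-280, so windows never wrap the calendar year (winter-crop wrap handling
is out of scope). Crop masks keep 90% of each county's pixels, thresholding a
smooth field within each county so that every county always contributes crop
pixels and the county-table row count stays exactly
`counties x years`.

True pixel yield is

```
Y = b0 + b_gpp * cumGPP + b_lai * meanLAI + b_et * cumET
       - b_ts2 * (cumTs - t_opt)^2 + b_clay * clay + eps
```

where the cumulative/mean features are computed *by the same
`window_cumulate()` used by the preprocessing stage*, so window consistency
is structural rather than approximate. The quadratic temperature term gives
the forest a genuine non-linearity to learn. Default coefficients
(`b0 = 1500, b_gpp = 5, b_lai = 400, b_et = 6, b_ts2 = 0.05, b_clay = 15,
t_opt = 380`) were chosen from a signal budget: they place mean yields near
7,500 kg/ha with a cross-county spread of roughly +/-1,500 kg/ha, safely
inside the attainable ranges used for screening (maize 500-15,000, wheat
500-13,000 kg/ha), with county observation noise (100 kg/ha) far below the
county-level signal and pixel noise (300 kg/ha) large enough that
point-scale validation is visibly harder than county-scale validation — the
scale gap the validation suite is meant to exhibit. Configurations whose
implied yields fall systematically outside the attainable range are rejected
loudly; clipping would silently distort the truth.

County yields are crop-pixel means of the truth plus Gaussian noise; county
planting areas are `crop pixels x 100 ha x` a county-specific planted
fraction drawn in 0.2-0.6, so clean tables sit below the 10,000-ha screening
threshold. Flux towers are built *backwards* from the ET stack at the tower
pixel: corrected latent heat matches the stack exactly, daily closure ratios
jitter around the configured target, and sensible heat follows a fixed Bowen
ratio of 0.4. QC plus re-cumulation therefore reconstructs the gridded ET at
the tower, giving the pairing stage a known zero-bias reference.

What the generator does *not* emulate: real sensor retrieval error
structure (correlated, view-angle- and cloud-dependent), mixed pixels and
sub-pixel crop fractions, reprojection artefacts, county shapes more complex
than blocks, multi-crop rotations, and yield-reporting biases. Passing the
recovery tests shows the chain is correct and well-calibrated on smooth
fields with known truth — not that the accuracy figures transfer to real
archives.

## Planted outliers

`inject_outliers()` plants records that each violate exactly one screening
rule, in distinct counties, recording the intended class in an audit column.
One subtlety: with an inclusive per-county mean/SD, the largest standardised
deviation one of `n` values can attain is `(n-1)/sqrt(n)`, so a 3-SD violator
needs at least 11 records in its county; the injector checks feasibility
numerically and refuses otherwise. The screening audit attributes each
removed row to the *first* rule it violates (bounds, then SD, then area), so
a below-bound record that is incidentally also 3 SD from its county mean is
counted once, and audit counts equal the injection spec exactly.

# Numerical and design choices

- **Composite membership** is inclusive on start day-of-year
  (`start <= d <= end`), with no fractional weighting — consistent with 8-day
  product semantics.
- **Missing composites** inside a window are tolerated up to 20% of the
  selected composites (configurable); a sum is rescaled by selected/valid, a
  mean uses valid layers. Beyond that the pixel is nodata.
- **Zonal statistic** is the unweighted mean over crop pixels; no area
  weighting.
- **Energy screening**: days with `Rn - G <= 0` are excluded rather than
  corrected — the Bowen rescaling is unstable there. 8-day cumulation
  gap-scales composites with at least 6 of 8 valid days by
  `nominal/valid` and reports sparser composites missing; the 46th composite
  spans the year's remaining 5 (or 6) days and is scaled to its own nominal
  length. The Bowen correction is applied at daily resolution.
- **Planting-area rule**: the literal reading (exclude counties *above*
  10,000 ha) is the default, with the direction exposed as a configuration
  enum and the audit making the consequence visible.
- **SD-rule scope** is per county across the study years, computed once on
  the original table (no re-estimation after removals), skipped and flagged
  for single-record counties.
- **Split tie-breaking**: when several rows tie at the global extreme, the
  first in table order is forced into training.
- **Seed discipline**: every stochastic stage draws a 31-bit sub-seed from
  the single pipeline seed and a stage label (`spawn_seed()`), so stages are
  reproducible independently of one another's consumption of the random
  stream; identical configuration and seed give bit-identical worlds,
  models and reports.
- **Adjusted R^2**: two forms are reported. `r2_conventional` is the
  adjusted squared Pearson correlation and drives every selection and
  acceptance property. `r2_var_ratio` is a variance-ratio form
  `1 - (1 - SSM/SSO)(n-1)/(n-m-1)` retained for comparability with a
  published formulation; it measures relative spread, not fit, and can
  mislead (it equals 1 whenever the estimate spread matches the observed
  spread), which is why it is reported but never used for decisions.
- **Moran's I** uses the standard squared-deviation denominator
  `n * sum_ij w_ij d_i d_j / (S * sum_i d_i^2)`; a printed form without the
  square is dimensionally inconsistent and is not implemented. Adjacency is
  queen contiguity on the county raster. Residual Moran's I on a validation
  split is computed on county-mean residuals over the sub-graph of counties
  present, and reported missing when fewer than three connected counties
  remain.
- **Sensitivity analysis** perturbs the *test* features of a fixed trained
  model (`v -> v * (1 + u)`, `u ~ Uniform(range)`, drawn independently per
  row and feature); the model is not retrained. Whether retraining was
  intended in the emulated protocol is ambiguous; perturbing a fixed model
  isolates input-error propagation from refitting effects, which is the
  question the analysis answers here.
- **CWP** uses the explicit unit factor 10 (kg/ha per mm to kg/m^3), a 1-mm
  floor on cumulative ET to guard the division, and population-SD regional
  summaries (divide by n, declared in the output).
- **Raster storage**: no geospatial raster stack is required at analysis
  time — rasters are plain matrices on a declared 1-km pixel-centre grid.
  On disk, `write_world()` uses ENVI flat-binary rasters (float64,
  band-sequential, plain-text headers readable by GDAL) plus a JSON
  manifest; float64 storage makes write/read round trips bit-exact, and CSV
  tables are written at 17 significant digits for the same reason. The
  nodata sentinel (-9999) is declared in the headers and the manifest, and
  writing data containing the sentinel as a valid value is an error.
- **Ts units** are degrees Celsius with a declared units flag; cumulative Ts
  is a plain in-window sum with no base-temperature threshold.

# Problem sizes

Tests and the acceptance script run the default 60 x 60 / 25-county /
3-year world (75 county-year records, ~165k raster cells per indicator-year).
Recovery properties are asserted as means over 10 world seeds; the
combination search trains 15 forests per seed; the permutation null of
Moran's I uses 500 permutations. These sizes keep the full suite under a
minute while leaving every statistical property comfortably testable.

# Known limitations

- The forest is trained on county means but applied to pixels; the resulting
  point-scale degradation is reproduced qualitatively, not calibrated to any
  particular real-world magnitude.
- Counties are rectangular blocks; queen contiguity on more intricate
  boundaries is exercised only in unit tests with irregular label rasters.
- Phenology windows never wrap the calendar year; winter-wheat seasons that
  straddle the year boundary need a wrap-aware windowing rule that is out of
  scope.
- Nearest-neighbour resampling assumes both grids share one projected
  coordinate system; reprojection is out of scope.
- `r2_var_ratio` is reported for fidelity only (see above); comparisons between
  the two adjusted R^2 forms on real data should expect them to diverge.
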