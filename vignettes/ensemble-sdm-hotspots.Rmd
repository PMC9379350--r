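---
title: "Ensemble SDMs and richness hotspot change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDMs and richness hotspot change: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

`nichecast` implements a complete presence-only ensemble species distribution
modeling (SDM) workflow and the downstream multi-species change analysis:
occurrence cleaning, predictor pruning, a 63-run ensemble per species scored
by the True Skill Statistic (TSS), binary range maps for current and future
climate, stacked richness and hotspot maps, and zonal change accounting. A
virtual-species generator makes the whole pipeline testable against known
truth. This vignette explains the model, every consequential parameter, and
the design decisions behind the implementation.

## The modeling problem

Given presence-only records of a species and gridded bioclimatic predictors,
an SDM estimates `P(presence | environment)` per grid cell. With no true
absences, pseudo-absences (random background points) stand in for the absence
class. Single algorithms disagree systematically, so an ensemble of seven
learners — GLM, GAM, MARS, ANN, GBM, RF and CTA — is fitted across three
independent pseudo-absence draws and three random calibration/evaluation
splits: `7 × 3 × 3 = 63` model runs per species.

Each run is scored on its held-out 30% by the True Skill Statistic,

```
TSS = sensitivity + specificity − 1,
```

which is prevalence-independent and ranges −1..1. Runs with held-out
`TSS > 0.6` (strict) are admitted and weighted proportionally to their TSS;
the ensemble suitability of a cell is the weighted mean of member
probabilities. The continuous map is binarized at the cutoff maximizing TSS,
recomputed on the *ensemble's own* predictions over the pooled held-out points
of all admitted runs — so the operational threshold is still out-of-sample.
Ties in the threshold scan break toward the lower cutoff, favoring
sensitivity; for a rare-plant conservation question, missing true habitat is
the costlier error. Future projections reuse the current-climate threshold
unchanged, because a future scenario offers no observations to re-threshold
on.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| pseudo-absences per set (`n_pa`) | 5000 | points | large random background; placed at cell centres, unique per cell |
| presence buffer (`buffer_km`) | 10 | km | background excluded near presences so the absence class is not contaminated |
| calibration fraction (`train_frac`) | 0.70 | — | stratified per class; 30% held out for TSS |
| admission gate (`tss_min`) | 0.6 | TSS | strict `>`; "good" discrimination floor |
| pseudo-absence sets / splits | 3 / 3 | — | averages over background and split randomness |
| collinearity threshold | 0.70 | &#124;r&#124; | grid-wide Pearson; see below |
| hotspot rule | `top_quartile` | — | ≥ 75th percentile of richness over occupied cells |
| elevation filter tolerance | 1000 | m | records further outside the species' reported range are treated as erroneous |

All randomness flows from a single integer seed through `derive_seeds()`, so
every ensemble, benchmark and acceptance run is exactly reproducible.

## Predictor pruning

`correlation_filter()` removes bioclimatic variables greedily in a
caller-supplied priority order until no retained pair has grid-wide Pearson
`|r| > 0.70`. The absolute value matters: a strongly *negative* correlation is
just as redundant as a positive one. The package ships
`bioclim_retained_default` (`BIO1, BIO2, BIO3, BIO7, BIO14, BIO18, BIO19`) —
the seven-variable set commonly retained for Himalayan studies — as an
overridable default, and `gcm_ensemble()` reduces multiple GCM stacks to their
cell-wise mean (NA propagating, so a cell missing in any model is missing in
the ensemble).

## Geodata without a GDAL stack

No GeoTIFF-capable R package is available in this environment, so the package
implements a minimal `raster_grid` S3 class and reads/writes the plain-text
ESRI ASCII grid format, with a mandatory `.crs` sidecar file naming the
coordinate system (`"geographic"`/`"EPSG:4326"`, `"projected-m"`,
`"projected-km"`). Cell areas on geographic grids use the spherical-quadrangle
formula `R²·Δλ·(sin φ₂ − sin φ₁)` with `R = 6371.0072` km, exact on the
sphere; projected grids use `xres × yres`. Zones arrive as GeoJSON polygons
(`read_zones_geojson()`) or as elevation bands cut from a DEM
(`elevation_bands()`, default width 500 m); rasterization assigns a cell to
the first listed zone containing its centre (with a warning on overlap),
using the even-odd rule via `mgcv::in.out`.

## Hotspots and change accounting

Binary maps of all species are stacked into a richness count
(`stack_richness()`). The *extent of suitability* is every cell suitable for
at least one species; a *hotspot* is a cell whose richness reaches the 75th
percentile (type-7 linear interpolation) of richness over occupied cells —
the top quartile of the occupied-cell distribution. The source description of
"top 25%" admits a second reading — cutting at the 25th percentile — which is
available as `rule = "p25"`; it is far more permissive (hotspots approach the
extent) and is not the default because "top quartile of richness" is the
standard usage. `zonal_change()` then sums masked cell areas per zone under
both scenarios and derives `change_km2` and `change_pct`; zones with zero
current area get an undefined (NA) percent change rather than an infinity.

## The synthetic generator and benchmark

`make_landscape()` builds spatially autocorrelated fields by FFT convolution
of white noise with a Gaussian kernel (sd = `autocorr_range` cells) on a
projected 1-km grid. Elevation is a rescaled field; annual mean temperature
(BIO1) follows it through a 6.5 °C/km lapse rate, so uphill is cooler — the
property that makes uniform warming push cool niches into scarcer high
terrain. `make_species()` defines truth as a logistic function (linear +
quadratic terms) of named predictors; `sample_presences()` draws records
proportional to suitability × an optional accessibility bias and thins them to
one per cell, mimicking real survey data.

`synthetic_benchmark()` (configuration versioned in
`inst/extdata/benchmark.json`) runs five cool-niche species — quadratic BIO1
responses with optima at the 6th–14th percentile of available temperature —
on a 100×100 km landscape with 150 presence draws, 1000 pseudo-absences and a
3-km buffer per species, projects a +2 °C future, and compares estimated
areas, hotspots and declines with truth. The sample sizes and buffer scale the
full-size study design (≈57,000 km², 5000 background points, 10 km buffer)
down proportionally to the 10,000-cell landscape so one benchmark fits in
minutes on one CPU. Known limitation: with sharply peaked niches and
suitability-proportional sampling, the sensitivity-favoring threshold tends to
*overestimate* small ranges; at some seeds a species' area error exceeds 30%
even though its ensemble TSS is near 1 and hotspot recovery (Jaccard ≈ 0.8)
is good.

```{r benchmark, eval = FALSE}
bm <- synthetic_benchmark(seed = 1)
print(bm)
```

## Reporting

`make_area_table()` and `summarize_area_table()` produce the headline numbers
of a multi-species study: mean current/future suitable area, aggregate percent
change (change *of the mean*, not the mean of per-species changes — the two
differ materially when small ranges change by large percentages), counts of
declining species, and the largest/smallest range ratio.
`protected_area_share()` expresses zonal hotspot area as a share of the total.
The published tables of the Nepal Himalaya medicinal-plant study ship as CSV
fixtures (`nichecast_table("table1")` … `"table4"`) and are the
exact-reproduction surface for these functions:

```{r fixtures}
s <- summarize_area_table(nichecast_table("table2"))
c(mean_current = round(s$mean_current_km2),
  mean_future = round(s$mean_future_km2),
  change_pct = round(s$mean_change_pct, 1),
  n_declining = s$n_declining)
```

## Known limitations

- No dispersal, demography or biotic interactions: maps are climatic
  suitability, not occupancy.
- The MARS learner is a minimal in-package forward-selection hinge-basis
  logistic model (no established MARS implementation is installed here); it
  is the weakest of the seven members and relies on the TSS gate to be
  excluded when it underperforms.
- Shapefile input and GeoTIFF I/O are not supported; convert to GeoJSON and
  ESRI ASCII grids.
- Small-range species are prone to area overestimation (see the benchmark
  discussion above).
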