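# nichecast

Ensemble species distribution modeling (SDM) and richness-hotspot change
analysis for presence-only occurrence data, with a virtual-species synthetic
generator for end-to-end validation against known truth.

## The scientific problem

Given presence records of a species and gridded bioclimatic predictors
(BIO1–BIO19), an SDM estimates the probability of suitable habitat per ~1 km²
grid cell. With presence-only data, random background points ("pseudo-
absences", drawn outside a buffer around presences) stand in for the absence
class. Because individual algorithms disagree, a per-species ensemble is
fitted: seven learners (GLM, GAM, MARS, ANN, GBM, RF, CTA) × three
pseudo-absence sets × three random 70/30 calibration/evaluation splits = **63
model runs**. Each run is scored on its held-out 30% by the True Skill
Statistic,

```
TSS = sensitivity + specificity − 1,
```

and runs with held-out TSS > 0.6 form a TSS-weighted ensemble. The continuous
suitability map is binarized at the cutoff maximizing TSS on the ensemble's
pooled held-out predictions (ties break toward the lower cutoff, favoring
sensitivity), and future projections reuse that threshold. Binary maps of many
species are stacked into richness; cells in the top quartile of richness over
occupied cells are **hotspots**, and hotspot/suitable areas are accounted per
zone (protected areas, ecoregions, provinces, elevation bands) under current
and future climate.

## Worked example

A synthetic landscape with known truth, one species, current and +2 °C
climates:

```r
library(nichecast)

land <- make_landscape(seed = 42, shape = c(60, 60))   # 60x60 km, 1 km cells
species <- make_species(land,
  coefficients = list(intercept = 3, linear = c(BIO1 = 1.4, BIO14 = 0.05),
                      quadratic = c(BIO1 = -0.2)),
  species_id = "demo-plant")
occ <- sample_presences(species, n = 120, seed = 7)    # 116 unique cells

predictors <- stack_subset(land, bioclim_retained_default)
ens <- fit_species_ensemble(occ, predictors, n_pa = 400, buffer_km = 3,
                            seed = 99)
print(ens)
#> <species_ensemble> 56/63 runs admitted (TSS > 0.60), status ok
#>   ensemble threshold 0.514, pooled held-out TSS 0.959

current <- predict_suitability(ens, predictors)
future <- predict_suitability(
  ens, shift_climate(predictors, scenario_shift(add = c(BIO1 = 2))))
print(current)
#> <ensemble_prediction> 'demo-plant' (current): threshold 0.514, 1234 suitable cells
print(future)
#> <ensemble_prediction> 'demo-plant' (future): threshold 0.514, 997 suitable cells

areas <- cell_area_km2(land$layers$elev)
make_area_table(list(current), list(future), areas)
#>      species area_current_km2 area_future_km2 change_km2
#> 1 demo-plant             1234             997       -237

species_area(species$true_binary, areas)  # the known true range
#> [1] 1397
```

Warming shrinks the cool-adapted species' range, and the estimated current
area (1234 km²) sits close to the known truth (1397 km²). With several
species, `stack_richness()`, `hotspot_map()`, `extent_map()` and
`zonal_change()` complete the multi-species analysis;
`summarize_area_table()` produces the headline statistics.

The package also ships, as CSV fixtures, the published per-species and zonal
tables of the Nepal Himalaya medicinal-plant study it re-implements
(`nichecast_table("table1")` … `"table4"`), which the reporting functions
reproduce exactly:

```r
s <- summarize_area_table(nichecast_table("table2"))
round(c(s$mean_current_km2, s$mean_future_km2, s$mean_change_pct), 1)
#> [1] 5820.9 5215.1  -10.4
```

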