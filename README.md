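# vegprecip

Vegetation greenness does not respond to rainfall instantaneously: soil
moisture buffers precipitation over weeks to months, so the NDVI of a grass
pixel in a semi-arid steppe may track the rain that fell one or two months
ago, accumulated over several months. `vegprecip` implements a complete
gridded pipeline for quantifying this lagged, cumulative response and for
attributing its spatial pattern to climatic and biogeographical gradients.
It is aimed at ecohydrologists and remote-sensing analysts working with
monthly NDVI and climate rasters (0.5°-style grids), and it ships a
synthetic-data generator with a known embedded response structure so every
stage of the pipeline can be validated end to end without any downloads.

## The statistic

For each pixel, growing-season month *i* (April–October) and design
combination *j* of a time lag *l* ∈ {0,…,3} and cumulation period
*c* ∈ {1,…,6} months, the package computes the second-order partial
correlation between the year-indexed NDVI anomaly series and the
precipitation anomaly accumulated over the window covering months
*l* … *l* + *c* − 1 before month *i*, controlling for temperature and
radiation anomalies accumulated over the same window:

    r_{i,j} = pcor( NDVIano_i , PRano_{i,j} | TMPano_{i,j}, RADano_{i,j} )

with the classical recursion

    r_{12,3}  = (r_12 − r_13 r_23) / sqrt((1 − r_13²)(1 − r_23²))
    r_{12,34} = (r_{12,3} − r_{14,3} r_{24,3}) / sqrt((1 − r_{14,3}²)(1 − r_{24,3}²))

Anomalies are deviations from the per-calendar-month climatology over the
base period (default 1982–2015). The 7 × 24 = 168 monthly analyses per
pixel are reduced by signed maxima, `r_j = max_i r_{i,j}` and
`r_max = max_j r_j`, giving per-pixel best-window maps (best lag, best
cumulation period) and an overall response-strength map. Significance uses
the two-sided *t* test with `df = n − 2 − 2`.

Supporting modules compute:

* precipitation-characteristic indices — mean annual precipitation (MAP),
  fraction of precipitation days (FPD), and the precipitation concentration
  index `PCI = 100 · Σ p_i² / (Σ p_i)²` over the 12 monthly totals — plus
  threshold selection of pixels inside MAP 150–500 mm, FPD 0.075–0.275,
  PCI 19–23, the ranges where precipitation sensitivity peaks;
* the Angstrom estimate of solar radiation from sunshine hours,
  `R_s = (a_s + b_s · n/N) · R_a`;
* seasonal correlation modes Ra₀, Ra₋₁, Ra₍₋₁,₀₎, Ra₍₋₂,₋₁₎ relating
  seasonal NDVI (spring/summer/autumn) to same-season, previous-season and
  two-season precipitation windows;
* attribution: binned averages of `r_max` along MAP/FPD/PCI and
  topographic/soil gradients (50 mm / 0.025 / 1 / 1000 m / 1-unit bins,
  bins under 10 pixels excluded), box statistics (5/25/50/75/95th
  percentiles) and per-zone 24-combination median profiles over ecological
  zones defined as land-cover × ecoregion intersections.

All stacks are exchanged as CF-style NetCDF `(time, lat, lon)` files.

## Worked example

```r
library(vegprecip)

cfg     <- synth_config(n_lat = 15, n_lon = 15, seed = 42)
climate <- generate_climate(cfg)          # precip, temp, radiation, wet days
land    <- generate_landscape(cfg)        # ecozones, elevation, built-up ...
veg     <- generate_ndvi(climate, cfg, landscape = land)

qc   <- qc_mask(veg$ndvi, land$builtup)
cube <- monthly_lagcum_correlations(
  monthly_anomalies(veg$ndvi),      monthly_anomalies(climate$precip),
  monthly_anomalies(climate$temp),  monthly_anomalies(climate$radiation),
  mask = qc)
print(cube)
#> correlation_cube: 7 months x 24 combos x 15 x 15 grid, 34 analysis years (alpha = 0.05)

summ <- max_over_combos(max_over_months(cube), cube)
median(summ$r_max, na.rm = TRUE)
#> [1] 0.987
significance_summary(cube, qc)$percent_significant
#> [1] 100
```

`r_max` near 1 and 100% significance are what the generator's default
moderate-noise regime (noise SD = 0.3 × effect size) should produce.
Comparing the best-window maps against the generator's truth table shows
the point of the design — the embedded (lag, cumulation) window is
recovered almost everywhere:

```r
tr  <- veg$truth
rec <- tr$recoverable & as.vector(qc$valid)
mean(as.vector(summ$best_lag)[rec] == tr$lag[rec] &
     as.vector(summ$best_cumper)[rec] == tr$cum[rec])
#> [1] 0.982
```

The full pipeline — generation, QC, anomalies, indices, the monthly cube,
seasonal modes, attribution tables, and a hash manifest — runs from one
configuration:

```r
res <- run_full(default_pipeline_config(seed = 42), out_dir = "run1")
```

or from the shell via the thin CLI shipped in `inst/cli/`:

```sh
Rscript inst/cli/vegprecip run-all --seed 42 --out run1
```

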