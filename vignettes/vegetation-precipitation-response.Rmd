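---
title: "Methods: lagged partial-correlation analysis of vegetation response to precipitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged partial-correlation analysis of vegetation response to precipitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegprecip)
```

## The model

Vegetation activity integrates water supply over time. The working model of
this package is that a pixel's monthly NDVI anomaly is linearly related to
the precipitation anomaly accumulated over some window of recent months,
after the confounding influence of temperature and radiation anomalies is
removed. The analysis therefore estimates, for every pixel, growing-season
month $i \in \{4,\dots,10\}$ and combination $j$ of a lag
$l \in \{0,\dots,3\}$ and cumulation period $c \in \{1,\dots,6\}$ months,

$$ r_{i,j} = \operatorname{pcor}\!\left(\mathrm{NDVIano}_i,\
\mathrm{PRano}_{i,j} \mid \mathrm{TMPano}_{i,j}, \mathrm{RADano}_{i,j}\right), $$

a second-order partial correlation over one sample per analysis year. The
window of combination $(l, c)$ covers months $l, l+1, \dots, l+c-1$ before
the current month; lag 0 with cumulation 1 is the current month itself,
lag 2 with cumulation 4 sums months 2–5 before. Windowed predictors are
sums of monthly anomalies, where an anomaly is the departure from that
calendar month's mean over the base period (default 1982–2015; a leading
year of climate data exists only so that April of the first analysis year
can reach 8 months back, the deepest window of the design).

The $7 \times 24 = 168$ monthly coefficients per pixel are summarised by
signed maxima: $r_j = \max_i r_{i,j}$ removes vegetation-phenology timing
from each temporal pattern, and $r_{\max} = \max_j r_j$ measures the
overall strength of the precipitation–vegetation relationship regardless
of temporal pattern. Restricting the argmax to the four 1-month-cumulation
combinations gives the best-lag map; restricting to the six lag-0
combinations gives the best-cumulation map.

Assumptions worth keeping in mind: linearity of the response within the
sample; one value per year per month keeps samples serially uncorrelated
to first order (no adjustment for interannual autocorrelation is made);
and the controls enter linearly through the same window as precipitation.

## Statistical kernel

The partial correlation is computed by the textbook recursion on Pearson
coefficients,
$$ r_{12,3} = \frac{r_{12} - r_{13} r_{23}}{\sqrt{(1-r_{13}^2)(1-r_{23}^2)}},
\qquad
r_{12,34} = \frac{r_{12,3} - r_{14,3}\, r_{24,3}}{\sqrt{(1-r_{14,3}^2)(1-r_{24,3}^2)}}, $$
and the test suite verifies on thousands of random quadruplets that the
recursion agrees with the independent regression-residual construction
(correlating the residuals of each variable on both controls) to within
$10^{-10}$. Significance is a two-sided $t$ test with
$t = r\sqrt{\mathrm{df}/(1-r^2)}$ and $\mathrm{df} = n - 2 - k$ for $k$
controls; two-sided because both response signs are scientifically
meaningful. $|r| = 1$ maps to $p = 0$ by convention.

Missing data are handled pairwise-complete on the full four-variable
tuple: a year is dropped for all four series if any one of them is missing
there, so every Pearson coefficient entering the recursion shares one
sample. Degenerate cases — constant series, controls perfectly correlated
with a variable — propagate as missing cells, never as zeros.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| significance level $\alpha$ | 0.05 | — | conventional 95% level |
| growing season | Apr–Oct | months | snow-free activity window |
| seasons | Apr–May, Jun–Aug, Sep–Oct | months | spring/summer/autumn split of the growing season |
| winter (non-growing) | Nov–Mar | months | completes the partition; crosses the year boundary and is labelled by its Jan–Mar year |
| base period | 1982–2015 | years | climatology; applied also to the lead year |
| control window | `matched` | — | controls accumulate over the same window as precipitation; `lag0` mode available |
| MAP/FPD/PCI thresholds | 150–500 mm, 0.075–0.275, 19–23 | — | ranges where precipitation sensitivity peaks; closed intervals |
| bin widths | 50 mm, 0.025, 1; 1000 m, 1, 0.1 g cm⁻³, 50 mm | covariate units | gradient resolution for MAP, FPD, PCI, elevation, CTI, SBD, PAWC |
| minimum bin/zone population | 10 | pixels | suppresses noisy summaries |
| Angstrom $a_s, b_s$ | 0.25, 0.50 | — | standard FAO-56 coefficients when no local calibration exists |

## Design choices where the method was genuinely open

* **Control windows.** Accumulating temperature and radiation over the
  same lag/cumulation window as precipitation keeps the partialling
  symmetric in the three climate drivers; fixing the controls at lag 0 is
  available as a configuration switch (`controls_window = "lag0"`).
* **Signed maxima.** $r_j$ and $r_{\max}$ maximise the signed coefficient,
  so pixels dominated by negative correlations show negative maxima rather
  than absolute values. Ties break towards the smallest lag, then the
  smallest cumulation period — deterministic and biased towards the most
  parsimonious temporal pattern.
* **Any-significant flag.** A pixel counts as significantly responding if
  at least one of its 168 monthly analyses rejects at $\alpha$; the
  $r_{\max}$ map is masked accordingly. No multiple-testing correction is
  applied across the 168 analyses or across pixels; the per-pixel
  any-of-24 rejection rate under the null is therefore well above
  $\alpha$ (the acceptance script measures it).
* **Seasonal anomalies** are anomalies-of-aggregates: each seasonal sum or
  mean is re-centred on its own base-period mean. For means over fixed
  month windows this is mathematically identical to aggregating monthly
  anomalies; for precipitation sums the two differ only by a constant
  factor, which correlation ignores.
* **PCI per year, then averaged.** The alternative — PCI of the mean
  monthly climatology — smooths interannual variation in concentration and
  yields systematically lower values; both modes are implemented
  (`pci_map(mode = )`), per-year averaging is the default.
* **Area weights** for national series are $\cos(\text{latitude})$,
  renormalised over valid pixels at each time step.
* **Quantiles** in zonal box statistics interpolate linearly between order
  statistics (R type 7).
* **Bins** are left-closed, right-open, anchored at zero.
* **Winter** is November–March, so the four seasons partition the year and
  "previous season" arithmetic is well defined for spring.

## The synthetic world

`synth_config()` defines the study conditions. Climate: monthly
precipitation is gamma-distributed around a 12-value seasonal cycle
(default ≈ 360 mm yr⁻¹ concentrated in summer — a semi-arid monsoon-timed
regime, the setting where precipitation sensitivity is strongest),
temperature and radiation are cosine seasonal cycles peaking in July plus
Gaussian noise, wet-day counts and sunshine hours derive from monthly
wet-day fractions. The gamma marginal guarantees non-negative, skewed
rainfall so MAP, FPD and PCI behave realistically; dispersion 0 collapses
every variable onto its stated cycle.

NDVI is a baseline greenness cycle plus the embedded anomaly response

$$ \beta\, z(P_{\text{acc}}) + \gamma\, z(T_{\text{acc}}) +
   \delta\, z(R_{\text{acc}}) + \mathcal{N}(0, \sigma), $$

where each pixel has a true window $(l^\*, c^\*)$ drawn over the full
design, all three climate drivers act through that same window, and
$z(\cdot)$ standardises per pixel over the generation period so that
$\beta$ is scale-free and recovery difficulty is governed by
$\sigma/|\beta|$ alone. Defaults $\beta = 0.04$, $\gamma = 0.015$,
$\delta = 0.01$, $\sigma = 0.012$ NDVI units put the generator in the
moderate-noise regime $\sigma = 0.3\,\beta$. Accumulating the controls over
the pixel's response window (rather than sampling them at the current
month) makes the generative model coherent with the matched-control
analysis; with current-month control effects, part of the temperature and
radiation signal would survive the partialling at lagged windows and
systematically bias window selection.

Landscape: land cover is drawn per pixel from configurable class
proportions, ecoregions are contiguous latitude bands, ecological zones
are their intersection; elevation, CTI and soil attributes are smooth
random surfaces; built-up pixels are flagged at a configured fraction
(default 2%).

What the generator deliberately does **not** emulate: spatial
autocorrelation of climate noise, realistic monsoon dynamics, snow
processes, sensor artefacts beyond a simple sub-monthly depression for the
maximum-value-composite test, and nonlinear or threshold vegetation
responses. Passing tests on this world therefore demonstrate that the
statistical machinery is correct and well calibrated — not that real NDVI
obeys the linear model.

## Verification and problem sizes

The test suite pins every operation to an independent oracle (regression
residuals, nested-loop aggregation and binning, sort-based quantiles) and
checks the design's statistical guarantees at these scales, chosen to give
tight Monte-Carlo error while keeping the default run light:

* null calibration on a 50 × 50 grid (2 500 independent pixels, 34
  analysis years): the mean rejection rate of the $t$ test at
  $\alpha = 0.05$ over all 168 analyses per pixel must sit within three
  standard errors of 0.05;
* window recovery on 30 × 30 grids: at $\sigma = 0.3\,|\beta|$ the argmax
  over the 24-combination design must match the true $(l^\*, c^\*)$
  exactly for at least 90% of recoverable pixels; at $\sigma = |\beta|$
  the recovered lag must be within ±1 month for at least 70%;
* brute-force equality of the full cube on 3 × 3 grids to $10^{-12}$,
  and of the recursion against the residual oracle on 1 000 random
  quadruplets to $10^{-10}$;
* byte-identical output manifests across repeated runs of the default
  20 × 20 pipeline under one seed.

`scripts/acceptance.R` recomputes all of these from scratch under a
user-supplied seed.

## Known limitations

* No adjustment of effective sample size for serial correlation within the
  year-indexed series; significance is nominal under the independence
  assumption.
* No field-wise (across-pixel) multiple-testing control.
* The NetCDF reader expects the package's own CF-style layout
  (`months since` time axis); arbitrary third-party calendars are not
  parsed. GeoTIFF ingestion is not provided; NetCDF is the interchange
  format.
* Grids are regular lat/lon only — no projections or curvilinear grids.
* The Angstrom step takes extraterrestrial radiation $R_a$ and maximum
  sunshine duration $N$ as inputs; it does not derive them from latitude
  and day of year.
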