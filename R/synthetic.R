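#' Configuration of the synthetic gridded experiment
#'
#' Bundles every parameter of the synthetic world: grid size, years, seasonal
#' climate cycles with their dispersions, and the embedded vegetation
#' response. Each pixel responds to the precipitation anomaly accumulated
#' over a true window (lag `l*` in 0–3 months, cumulation `c*` in 1–6
#' months), plus temperature and radiation effects and Gaussian noise:
#' `NDVIano(t) = beta * z(Pacc) + gamma * z(Tano) + delta * z(Rano) + N(0, noise_sd)`,
#' with all predictors standardised per pixel over the generation period so
#' `beta` is in NDVI units per standard deviation of accumulated
#' precipitation anomaly and recovery difficulty is governed by
#' `noise_sd / |beta|` alone.
#'
#' The default monthly precipitation means describe a semi-arid
#' monsoon-timed regime (annual total about 360 mm, wet-day fraction about
#' 0.16, concentrated summer rain) — the precipitation conditions under
#' which vegetation is most precipitation-sensitive.
#'
#' @param n_lat,n_lon Grid dimensions.
#' @param years Inclusive year range; default 1981:2015 (the leading year
#'   exists to feed lagged accumulation windows).
#' @param seed Integer master seed; per-variable substreams are derived from
#'   it deterministically.
#' @param precip_mean 12 monthly mean precipitation totals (mm).
#' @param precip_cv Coefficient of variation of monthly precipitation
#'   (gamma-distributed; 0 = deterministic cycle).
#' @param temp_mean,temp_amplitude,temp_sd Temperature seasonal cycle (degC)
#'   and noise SD.
#' @param rad_mean,rad_amplitude,rad_sd Radiation seasonal cycle
#'   (MJ m-2 d-1) and noise SD.
#' @param wetday_frac 12 monthly mean wet-day fractions.
#' @param wetday_sd SD of the wet-day fraction noise (0 = deterministic).
#' @param sunshine_max Maximum possible daily sunshine hours `N`.
#' @param sunshine_sd SD of the sunshine-fraction noise.
#' @param beta,gamma_t,delta_r Effect sizes (NDVI units per SD of predictor);
#'   scalars or `(n_lat, n_lon)` matrices.
#' @param noise_sd NDVI anomaly noise SD (scalar or matrix). The default is
#'   0.3 of the default `beta`, the moderate-noise regime in which the true
#'   window should be recoverable.
#' @param lag_field,cum_field Optional `(n_lat, n_lon)` integer matrices of
#'   true lags (0–3) and cumulation periods (1–6); drawn uniformly over the
#'   design if `NULL`.
#' @param ndvi_base_mean,ndvi_base_amplitude Baseline NDVI seasonal cycle.
#' @param builtup_fraction Fraction of pixels flagged built-up.
#' @param n_landcover,n_ecoregion Landscape structure: number of land-cover
#'   classes (per-pixel multinomial) and of ecoregions (contiguous latitude
#'   bands).
#' @param landcover_props Optional class proportions (default equal).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_lat = 20, n_lon = 20, years = 1981:2015, seed = 42,
                         precip_mean = c(3, 4, 8, 15, 30, 55, 90, 80, 45, 20, 8, 4),
                         precip_cv = 0.6,
                         temp_mean = 8, temp_amplitude = 15, temp_sd = 1,
                         rad_mean = 15, rad_amplitude = 8, rad_sd = 1.5,
                         wetday_frac = c(0.06, 0.07, 0.09, 0.12, 0.18, 0.25,
                                         0.30, 0.28, 0.20, 0.12, 0.08, 0.06),
                         wetday_sd = 0.05,
                         sunshine_max = 12, sunshine_sd = 0.05,
                         beta = 0.04, gamma_t = 0.015, delta_r = 0.01,
                         noise_sd = 0.012,
                         lag_field = NULL, cum_field = NULL,
                         ndvi_base_mean = 0.3, ndvi_base_amplitude = 0.15,
                         builtup_fraction = 0.02,
                         n_landcover = 4, n_ecoregion = 2,
                         landcover_props = NULL) {
  stopifnot(n_lat >= 1, n_lon >= 1, length(years) >= 3,
            length(precip_mean) == 12, all(precip_mean >= 0), precip_cv >= 0,
            temp_sd >= 0, rad_sd >= 0, length(wetday_frac) == 12,
            all(wetday_frac >= 0 & wetday_frac <= 1), wetday_sd >= 0,
            sunshine_max > 0, builtup_fraction >= 0, builtup_fraction <= 1)
  as_field <- function(x, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(n_lat, n_lon)))
        stop(nm, " matrix has wrong dimensions", call. = FALSE)
      x
    } else matrix(x, n_lat, n_lon)
  }
  cfg <- list(n_lat = n_lat, n_lon = n_lon, years = as.integer(years),
              seed = as.integer(seed),
              precip_mean = precip_mean, precip_cv = precip_cv,
              temp_mean = temp_mean, temp_amplitude = temp_amplitude,
              temp_sd = temp_sd,
              rad_mean = rad_mean, rad_amplitude = rad_amplitude,
              rad_sd = rad_sd,
              wetday_frac = wetday_frac, wetday_sd = wetday_sd,
              sunshine_max = sunshine_max, sunshine_sd = sunshine_sd,
              beta = as_field(beta, "beta"),
              gamma_t = as_field(gamma_t, "gamma_t"),
              delta_r = as_field(delta_r, "delta_r"),
              noise_sd = as_field(noise_sd, "noise_sd"),
              lag_field = if (is.null(lag_field)) NULL else as_field(lag_field, "lag_field"),
              cum_field = if (is.null(cum_field)) NULL else as_field(cum_field, "cum_field"),
              ndvi_base_mean = ndvi_base_mean,
              ndvi_base_amplitude = ndvi_base_amplitude,
              builtup_fraction = builtup_fraction,
              n_landcover = n_landcover, n_ecoregion = n_ecoregion,
              landcover_props = landcover_props)
  if (!is.null(cfg$lag_field) &&
      !all(cfg$lag_field %in% 0:3)) stop("true lags must be 0..3", call. = FALSE)
  if (!is.null(cfg$cum_field) &&
      !all(cfg$cum_field %in% 1:6)) stop("true cumulation periods must be 1..6",
                                         call. = FALSE)
  if (any(cfg$noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "synth_config")
}

synth_axes <- function(config) {
  # a 0.5-degree window in mid-latitudes; exact location is immaterial
  grid_axes(seq(50 - 0.25, by = -0.5, length.out = config$n_lat),
            seq(100 + 0.25, by = 0.5, length.out = config$n_lon))
}

# deterministic substreams: each generated variable re-seeds from the master
# seed plus a fixed offset, so outputs do not depend on generation order
substream <- function(config, offset) set.seed(config$seed + offset)

synth_calendar <- function(config) {
  yrs <- rep(config$years, each = 12L)
  mos <- rep(1:12, times = length(config$years))
  list(years = yrs, months = mos, n = length(yrs))
}

#' Generate synthetic monthly climate stacks
#'
#' Precipitation is gamma-distributed around the configured monthly means
#' (shape `1/cv^2`, guaranteeing non-negative skewed rainfall so PCI and FPD
#' behave realistically); temperature and radiation are a seasonal cosine
#' cycle (peaking in July) plus Gaussian noise; wet-day counts and sunshine
#' hours derive from the monthly wet-day fraction. Fully reproducible from
#' the config seed; dispersion 0 collapses each variable onto its stated
#' seasonal cycle.
#'
#' @param config A [synth_config()].
#' @return A list of [monthly_raster()]s: `precip`, `temp`, `radiation`,
#'   `wet_days`, `sunshine`.
#' @export
generate_climate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ax <- synth_axes(config)
  cal <- synth_calendar(config)
  npix <- config$n_lat * config$n_lon
  dims <- c(cal$n, config$n_lat, config$n_lon)
  seasonal <- function(mean, amp) mean + amp * cos(2 * pi * (cal$months - 7) / 12)

  substream(config, 1L)
  pr <- array(NA_real_, dims)
  mu <- config$precip_mean[cal$months]
  if (config$precip_cv == 0) {
    pr[] <- rep(mu, npix)
  } else {
    shape <- 1 / config$precip_cv^2
    for (t in seq_len(cal$n))
      pr[t, , ] <- if (mu[t] == 0) 0 else
        stats::rgamma(npix, shape = shape, scale = mu[t] / shape)
  }

  substream(config, 2L)
  tc <- seasonal(config$temp_mean, config$temp_amplitude)
  tmp <- array(tc, dims)
  if (config$temp_sd > 0) tmp <- tmp + stats::rnorm(length(tmp), sd = config$temp_sd)

  substream(config, 3L)
  rc <- seasonal(config$rad_mean, config$rad_amplitude)
  rad <- array(rc, dims)
  if (config$rad_sd > 0) rad <- rad + stats::rnorm(length(rad), sd = config$rad_sd)
  rad <- pmax(rad, 0)

  substream(config, 4L)
  frac <- array(config$wetday_frac[cal$months], dims)
  if (config$wetday_sd > 0)
    frac <- frac + stats::rnorm(length(frac), sd = config$wetday_sd)
  frac <- pmin(pmax(frac, 0), 1)
  dim_t <- days_in_month(cal$years, cal$months)
  wd <- round(sweep(frac, 1, dim_t, "*"))

  substream(config, 5L)
  sfrac <- 1 - 0.7 * frac
  if (config$sunshine_sd > 0)
    sfrac <- sfrac + stats::rnorm(length(sfrac), sd = config$sunshine_sd)
  sun <- pmin(pmax(sfrac, 0), 1) * config$sunshine_max

  mk <- function(v, var) monthly_raster(ax, cal$years, cal$months, v, var)
  list(precip = mk(pr, "precip_mm"),
       temp = mk(tmp, "temp_C"),
       radiation = mk(rad, "radiation_MJ_m2_d"),
       wet_days = mk(wd, "wet_days"),
       sunshine = mk(sun, "sunshine_h"))
}

#' Generate synthetic NDVI with a known embedded response structure
#'
#' Builds monthly NDVI as a baseline seasonal greenness cycle plus an anomaly
#' that responds, per pixel, to the precipitation anomaly accumulated over
#' that pixel's true (lag, cumulation) window, to the current-month
#' temperature and radiation anomalies, and to Gaussian noise (see
#' [synth_config()]). Months too early for the pixel's window to fit inside
#' the generated record carry noise only; with the default 1981 lead year
#' this never touches an analysis month.
#'
#' @param climate Output of [generate_climate()].
#' @param config The same [synth_config()].
#' @param landscape Optional output of [generate_landscape()]; if given, the
#'   truth table carries each pixel's ecological zone id.
#' @param semimonthly If `TRUE`, also return paired sub-monthly composites
#'   whose per-month maximum reproduces the monthly NDVI (for testing the
#'   maximum value composite step).
#' @return A list: `ndvi` ([monthly_raster()]), `truth` (data frame with
#'   `lat_idx`, `lon_idx`, `lag`, `cum`, `beta`, `gamma`, `delta`,
#'   `noise_sd`, `zone_id`, `recoverable`), and optionally
#'   `ndvi_semimonthly` (list of two composite rasters).
#' @export
generate_ndvi <- function(climate, config, landscape = NULL,
                          semimonthly = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  pr <- climate$precip
  cal <- list(years = pr$years, months = pr$months, n = length(pr$years))
  n_lat <- config$n_lat; n_lon <- config$n_lon; npix <- n_lat * n_lon

  substream(config, 6L)
  lag <- if (is.null(config$lag_field))
    matrix(sample(0:3, npix, replace = TRUE), n_lat, n_lon) else config$lag_field
  cum <- if (is.null(config$cum_field))
    matrix(sample(1:6, npix, replace = TRUE), n_lat, n_lon) else config$cum_field

  # per-calendar-month anomalies over the full generation period
  ano_of <- function(r) {
    a <- r$values
    for (m in 1:12) {
      rows <- which(r$months == m)
      clim <- colMeans(r$values[rows, , , drop = FALSE], dims = 1)
      for (t in rows) a[t, , ] <- r$values[t, , ] - clim
    }
    a
  }
  zscale <- function(m) {
    mu <- colMeans(m); sd <- apply(m, 2, stats::sd)
    sd[sd == 0] <- 1
    sweep(sweep(m, 2, mu), 2, sd, "/")
  }
  pano <- ano_of(pr)
  tano <- ano_of(climate$temp)
  rano <- ano_of(climate$radiation)
  dim(pano) <- c(cal$n, npix); dim(tano) <- c(cal$n, npix)
  dim(rano) <- c(cal$n, npix)

  # anomalies accumulated over each pixel's true window (precipitation,
  # temperature and radiation alike, so the climate drivers act through one
  # temporal integration per pixel), standardised per pixel, computed per
  # (lag, cum) group from column cumulative sums
  lagv <- as.vector(lag); cumv <- as.vector(cum)
  window_z <- function(ano) {
    out <- matrix(0, cal$n, npix)
    cs <- rbind(0, apply(ano, 2, cumsum))
    for (l in sort(unique(lagv))) for (c in sort(unique(cumv))) {
      px <- which(lagv == l & cumv == c)
      if (!length(px)) next
      rows <- (l + c):cal$n  # earliest month with a full window
      acc <- cs[rows - l + 1, px, drop = FALSE] -
             cs[rows - l - c + 1, px, drop = FALSE]
      mu <- colMeans(acc); sd <- apply(acc, 2, stats::sd)
      sd[is.na(sd) | sd == 0] <- 1
      out[rows, px] <- sweep(sweep(acc, 2, mu), 2, sd, "/")
    }
    out
  }
  pacc <- window_z(pano)
  tz <- window_z(tano)
  rz <- window_z(rano)
  # months before a full window fits carry no climate response

  substream(config, 7L)
  noise <- matrix(stats::rnorm(cal$n * npix), cal$n, npix)
  noise <- sweep(noise, 2, as.vector(config$noise_sd), "*")

  anom <- sweep(pacc, 2, as.vector(config$beta), "*") +
    sweep(tz, 2, as.vector(config$gamma_t), "*") +
    sweep(rz, 2, as.vector(config$delta_r), "*") + noise
  base <- config$ndvi_base_mean +
    config$ndvi_base_amplitude * cos(2 * pi * (cal$months - 7) / 12)
  ndvi <- anom + base
  ndvi <- pmin(pmax(ndvi, -1), 1)
  dim(ndvi) <- c(cal$n, n_lat, n_lon)
  ndvi_r <- monthly_raster(pr$axes, cal$years, cal$months, ndvi, "ndvi")

  zone_id <- if (!is.null(landscape)) as.vector(landscape$ecozone$values)
             else rep(NA_integer_, npix)
  idx <- arrayInd(seq_len(npix), c(n_lat, n_lon))
  truth <- data.frame(lat_idx = idx[, 1], lon_idx = idx[, 2],
                      lag = lagv, cum = cumv,
                      beta = as.vector(config$beta),
                      gamma = as.vector(config$gamma_t),
                      delta = as.vector(config$delta_r),
                      noise_sd = as.vector(config$noise_sd),
                      zone_id = zone_id,
                      recoverable = abs(as.vector(config$beta)) > 0 &
                        as.vector(config$noise_sd) < abs(as.vector(config$beta)))
  out <- list(ndvi = ndvi_r, truth = truth)
  if (semimonthly) {
    substream(config, 8L)
    depress <- abs(stats::rnorm(length(ndvi), mean = 0.02, sd = 0.01))
    low <- pmax(ndvi - depress, -1)
    out$ndvi_semimonthly <- list(
      monthly_raster(pr$axes, cal$years, cal$months, ndvi, "ndvi"),
      monthly_raster(pr$axes, cal$years, cal$months, low, "ndvi"))
    # randomise which composite carries the maximum
    swap <- array(stats::runif(length(ndvi)) < 0.5, dim(ndvi))
    a <- out$ndvi_semimonthly[[1]]$values
    b <- out$ndvi_semimonthly[[2]]$values
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out$ndvi_semimonthly[[1]]$values <- a
    out$ndvi_semimonthly[[2]]$values <- b
  }
  out
}

# smooth random surface: coarse gaussian grid, bilinearly interpolated
smooth_field <- function(n_lat, n_lon, lo, hi, knots = 4) {
  ky <- max(2, min(knots, n_lat)); kx <- max(2, min(knots, n_lon))
  g <- matrix(stats::runif(ky * kx), ky, kx)
  yi <- seq(1, ky, length.out = n_lat); xi <- seq(1, kx, length.out = n_lon)
  y0 <- pmin(floor(yi), ky - 1); x0 <- pmin(floor(xi), kx - 1)
  fy <- yi - y0; fx <- xi - x0
  out <- matrix(0, n_lat, n_lon)
  for (i in seq_len(n_lat)) for (j in seq_len(n_lon)) {
    a <- g[y0[i], x0[j]]; b <- g[y0[i], x0[j] + 1]
    d <- g[y0[i] + 1, x0[j]]; e <- g[y0[i] + 1, x0[j] + 1]
    out[i, j] <- (1 - fy[i]) * ((1 - fx[j]) * a + fx[j] * b) +
      fy[i] * ((1 - fx[j]) * d + fx[j] * e)
  }
  lo + (hi - lo) * out
}

#' Generate synthetic static landscape maps
#'
#' Land cover is drawn per pixel from the configured class proportions;
#' ecoregions are contiguous latitude bands; the ecological-zone map is their
#' intersection (one zone per observed land-cover-within-ecoregion pair).
#' Elevation, CTI and soil attributes are smooth random surfaces; built-up
#' pixels are flagged at the configured fraction.
#'
#' @param config A [synth_config()].
#' @return A list of [static_map()]s: `landcover`, `ecoregion`, `ecozone`,
#'   `elevation`, `cti`, `sbd`, `pawc`, `builtup`.
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  ax <- synth_axes(config)
  n_lat <- config$n_lat; n_lon <- config$n_lon; npix <- n_lat * n_lon

  substream(config, 9L)
  props <- config$landcover_props
  if (is.null(props)) props <- rep(1 / config$n_landcover, config$n_landcover)
  lc <- matrix(sample.int(config$n_landcover, npix, replace = TRUE,
                          prob = props), n_lat, n_lon)
  band <- pmin(config$n_ecoregion,
               pmax(1L, ceiling(seq_len(n_lat) / n_lat * config$n_ecoregion)))
  er <- matrix(band, n_lat, n_lon)
  lc_map <- static_map(ax, lc, "landcover_class")
  er_map <- static_map(ax, er, "ecoregion_id")
  ez <- eco_zone_intersect(lc_map, er_map)

  substream(config, 10L)
  elev <- smooth_field(n_lat, n_lon, 500, 3000)
  cti <- smooth_field(n_lat, n_lon, 2, 10)
  sbd <- smooth_field(n_lat, n_lon, 1.0, 1.6)
  pawc <- smooth_field(n_lat, n_lon, 50, 300)

  substream(config, 11L)
  bu <- matrix(0L, n_lat, n_lon)
  nbu <- round(config$builtup_fraction * npix)
  if (nbu > 0) bu[sample.int(npix, nbu)] <- 1L

  list(landcover = lc_map, ecoregion = er_map, ecozone = ez,
       elevation = static_map(ax, elev, "elevation_m"),
       cti = static_map(ax, cti, "cti"),
       sbd = static_map(ax, sbd, "sbd_g_cm3"),
       pawc = static_map(ax, pawc, "pawc_mm"),
       builtup = static_map(ax, bu, "builtup_flag"))
}

#' Write or read a synthetic truth table
#'
#' Sidecar delimited text file keyed by (lat index, lon index), recording
#' each pixel's true response window and effect sizes.
#'
#' @param truth Truth data frame from [generate_ndvi()].
#' @param path File path (tab-separated, with header).
#' @return `read_truth_table` returns the data frame; `write_truth_table`
#'   returns `path` invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
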