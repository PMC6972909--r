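# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: partial correlations via regression residuals,
# aggregations and summaries via plain nested loops.

# first-order partial correlation via residuals of simple regressions
oracle_parcor1 <- function(x, y, z) {
  stats::cor(stats::resid(stats::lm(x ~ z)), stats::resid(stats::lm(y ~ z)))
}

# second-order partial correlation via residuals on both controls
oracle_parcor2 <- function(x, y, z1, z2) {
  stats::cor(stats::resid(stats::lm(x ~ z1 + z2)),
             stats::resid(stats::lm(y ~ z1 + z2)))
}

# a small monthly raster filled by a function f(t, i, j) (NA allowed)
toy_raster <- function(n_lat, n_lon, years, variable = "precip_mm",
                       f = function(t, i, j) t + i + j) {
  yrs <- rep(years, each = 12L); mos <- rep(1:12, length(years))
  v <- array(NA_real_, c(length(yrs), n_lat, n_lon))
  for (t in seq_along(yrs)) for (i in seq_len(n_lat)) for (j in seq_len(n_lon))
    v[t, i, j] <- f(t, i, j)
  ax <- grid_axes(seq(50 - 0.25, by = -0.5, length.out = n_lat),
                  seq(100 + 0.25, by = 0.5, length.out = n_lon))
  monthly_raster(ax, yrs, mos, v, variable, validate = FALSE)
}

toy_axes <- function(n_lat, n_lon) {
  grid_axes(seq(50 - 0.25, by = -0.5, length.out = n_lat),
            seq(100 + 0.25, by = 0.5, length.out = n_lon))
}

# brute-force cube assembly: loops over months, combos, years; window sums
# by hand; partial_second from the package's scalar API
oracle_cube <- function(ndvi_ano, p_ano, t_ano, r_ano, years,
                        controls_window = "matched") {
  combos <- design_combos()
  n_lat <- ndvi_ano$axes$n_lat; n_lon <- ndvi_ano$axes$n_lon
  out <- array(NA_real_, c(7, 24, n_lat, n_lon))
  key <- function(r) r$years * 12L + r$months - 1L
  for (im in 1:7) {
    i <- im + 3L
    for (jj in 1:24) {
      l <- combos$lag[jj]; cp <- combos$cumper[jj]
      cl <- if (controls_window == "matched") l else 0L
      for (px_i in seq_len(n_lat)) for (px_j in seq_len(n_lon)) {
        x <- y <- z1 <- z2 <- numeric(length(years))
        for (k in seq_along(years)) {
          t0 <- which(key(ndvi_ano) == years[k] * 12L + i - 1L)
          x[k] <- ndvi_ano$values[t0, px_i, px_j]
          y[k] <- sum(p_ano$values[(t0 - l - cp + 1):(t0 - l), px_i, px_j])
          z1[k] <- sum(t_ano$values[(t0 - cl - cp + 1):(t0 - cl), px_i, px_j])
          z2[k] <- sum(r_ano$values[(t0 - cl - cp + 1):(t0 - cl), px_i, px_j])
        }
        r <- tryCatch(partial_second(x, y, z1, z2)$r,
                      error = function(e) NA_real_)
        out[im, jj, px_i, px_j] <- r
      }
    }
  }
  out
}

# four random anomaly stacks ready for the correlation engine
make_anomaly_set <- function(n_lat, n_lon, years, seed) {
  set.seed(seed)
  mk <- function(var, lo, hi)
    monthly_anomalies(toy_raster(n_lat, n_lon, years, var,
                                 f = function(t, i, j) runif(1, lo, hi)),
                      range(years))
  list(ndvi = mk("ndvi", 0.05, 0.95), precip = mk("precip_mm", 0, 80),
       temp = mk("temp_C", -5, 25), rad = mk("radiation_MJ_m2_d", 5, 25))
}

# small synthetic world shared by several tests (cached per session)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_lat = 8, n_lon = 8, seed = 101)
      cl <- generate_climate(cfg)
      land <- generate_landscape(cfg)
      veg <- generate_ndvi(cl, cfg, landscape = land)
      cache <<- list(cfg = cfg, climate = cl, land = land, veg = veg)
    }
    cache
  }
})
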