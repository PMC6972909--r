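test_that("the design enumerates the 4 x 6 grid with Table-style windows", {
  d <- design_combos()
  expect_equal(nrow(d), 24)
  expect_equal(d$j, 1:24)
  expect_equal(d$j, d$lag * 6 + d$cumper)
  expect_equal(d$window[d$lag == 1 & d$cumper == 3], "1-3")
  expect_equal(d$window[d$lag == 0 & d$cumper == 5], "0-4")
  expect_equal(d$window[d$lag == 0 & d$cumper == 1], "0")
  expect_equal(d$window[d$lag == 2 & d$cumper == 4], "2-5")
  expect_equal(d$window[d$lag == 3 & d$cumper == 6], "3-8")
})

test_that("the cube runs 168 analyses per pixel and matches brute force", {
  an <- make_anomaly_set(3, 3, 1999:2010, seed = 51)
  years <- 2000:2010
  cube <- monthly_lagcum_correlations(an$ndvi, an$precip, an$temp, an$rad,
                                      years = years)
  expect_equal(dim(cube$r)[1:2], c(7L, 24L))
  expect_equal(prod(dim(cube$r)[1:2]), 168)
  ref <- oracle_cube(an$ndvi, an$precip, an$temp, an$rad, years)
  expect_equal(cube$r, ref, tolerance = 1e-12)
  # lag-0 control mode also matches its brute-force assembly
  cube0 <- monthly_lagcum_correlations(an$ndvi, an$precip, an$temp, an$rad,
                                       years = years,
                                       controls_window = "lag0")
  ref0 <- oracle_cube(an$ndvi, an$precip, an$temp, an$rad, years,
                      controls_window = "lag0")
  expect_equal(cube0$r, ref0, tolerance = 1e-12)
})

test_that("a common permutation of years leaves every cube cell unchanged", {
  an <- make_anomaly_set(2, 2, 1999:2012, seed = 52)
  years <- 2000:2012
  cube <- monthly_lagcum_correlations(an$ndvi, an$precip, an$temp, an$rad,
                                      years = years)
  set.seed(1)
  perm <- sample(years)
  cube_p <- monthly_lagcum_correlations(an$ndvi, an$precip, an$temp, an$rad,
                                        years = perm)
  expect_equal(cube_p$r, cube$r, tolerance = 1e-12)
})

test_that("a noiseless pixel correlates perfectly at its true combination", {
  cfg <- synth_config(n_lat = 2, n_lon = 2, seed = 6,
                      lag_field = matrix(1L, 2, 2),
                      cum_field = matrix(2L, 2, 2),
                      gamma_t = 0, delta_r = 0, noise_sd = 0)
  cl <- generate_climate(cfg)
  veg <- generate_ndvi(cl, cfg)
  cube <- monthly_lagcum_correlations(
    monthly_anomalies(veg$ndvi), monthly_anomalies(cl$precip),
    monthly_anomalies(cl$temp), monthly_anomalies(cl$radiation))
  j_true <- which(cube$combos$lag == 1 & cube$combos$cumper == 2)
  expect_true(all(abs(cube$r[, j_true, , ] - 1) < 1e-10))
})

test_that("monthly and combination maxima match loop oracles with NA skipping", {
  an <- make_anomaly_set(3, 2, 1999:2010, seed = 53)
  cube <- monthly_lagcum_correlations(an$ndvi, an$precip, an$temp, an$rad,
                                      years = 2000:2010)
  # inject missing months
  cube$r[2, 5, 1, 1] <- NA; cube$p[2, 5, 1, 1] <- NA
  cube$r[, 3, 2, 2] <- NA; cube$p[, 3, 2, 2] <- NA
  cube$r[1:6, 10, 3, 1] <- NA
  rj <- max_over_months(cube)
  for (jj in 1:24) for (i in 1:3) for (j in 1:2) {
    v <- cube$r[, jj, i, j]
    want <- if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    expect_equal(rj$r_j[jj, i, j], want)
  }
  # single surviving month carries its value through
  expect_equal(rj$r_j[10, 3, 1], cube$r[7, 10, 3, 1])
  summ <- max_over_combos(rj, cube)
  for (i in 1:3) for (j in 1:2) {
    v <- rj$r_j[, i, j]
    if (all(is.na(v))) { expect_true(is.na(summ$r_max[i, j])); next }
    expect_equal(summ$r_max[i, j], max(v, na.rm = TRUE))
    expect_equal(summ$best_j[i, j], which.max(v))
  }
  expect_true(all(summ$r_max >= rj$r_j[5, , ] | is.na(rj$r_j[5, , ])))
})

test_that("ties break towards the smallest lag, then smallest cumulation", {
  rj <- structure(list(axes = toy_axes(1, 1), combos = design_combos(),
                       months = 4:10, n = 30, alpha = 0.05,
                       r_j = array(0.5, c(24, 1, 1)),
                       p_at_max = array(0.01, c(24, 1, 1)),
                       month_at_max = array(7L, c(24, 1, 1))),
                  class = "rj_maps")
  summ <- max_over_combos(rj)
  expect_equal(summ$best_lag[1, 1], 0L)
  expect_equal(summ$best_cumper[1, 1], 1L)
})

test_that("best-lag and best-cumulation shares partition the selected pixels", {
  an <- make_anomaly_set(4, 4, 1999:2012, seed = 54)
  cube <- monthly_lagcum_correlations(an$ndvi, an$precip, an$temp, an$rad,
                                      years = 2000:2012)
  rj <- max_over_months(cube)
  summ <- max_over_combos(rj, cube)
  bl <- best_lag_map(rj, summ)
  bc <- best_cum_map(rj, summ)
  expect_equal(bl$shares$lag, 0:3)
  expect_equal(bc$shares$cumper, 1:6)
  if (sum(bl$shares$count) > 0)
    expect_equal(sum(bl$shares$percent), 100, tolerance = 1e-9)
  if (sum(bc$shares$count) > 0)
    expect_equal(sum(bc$shares$percent), 100, tolerance = 1e-9)
  # the best-lag map restricts to 1-month cumulation combos
  sub <- rj$r_j[which(rj$combos$cumper == 1), , ]
  for (i in 1:4) for (j in 1:4)
    expect_equal(bl$lag_map[i, j], which.max(sub[, i, j]) - 1L)
})

test_that("high-signal synthetic pixels recover their true window", {
  w <- small_world()
  qc <- qc_mask(w$veg$ndvi, w$land$builtup)
  cube <- monthly_lagcum_correlations(
    monthly_anomalies(w$veg$ndvi), monthly_anomalies(w$climate$precip),
    monthly_anomalies(w$climate$temp),
    monthly_anomalies(w$climate$radiation), mask = qc)
  rj <- max_over_months(cube)
  summ <- max_over_combos(rj, cube)
  tr <- w$veg$truth
  ok <- tr$recoverable & as.vector(qc$valid)
  hit <- as.vector(summ$best_lag)[ok] == tr$lag[ok] &
    as.vector(summ$best_cumper)[ok] == tr$cum[ok]
  expect_gt(mean(hit), 0.9)
  # with strong embedded signal every pixel is significant
  sig <- significance_summary(cube, qc)
  expect_equal(sig$percent_significant, 100)
  expect_true(all(summ$r_max[qc$valid] >= 0.7))
})

test_that("an all-signal noiseless field is 100% significant", {
  cfg <- synth_config(n_lat = 3, n_lon = 3, seed = 8, noise_sd = 0,
                      gamma_t = 0, delta_r = 0)
  cl <- generate_climate(cfg)
  veg <- generate_ndvi(cl, cfg)
  cube <- monthly_lagcum_correlations(
    monthly_anomalies(veg$ndvi), monthly_anomalies(cl$precip),
    monthly_anomalies(cl$temp), monthly_anomalies(cl$radiation))
  sig <- significance_summary(cube)
  expect_equal(sig$percent_significant, 100)
  expect_gte(sig$percent_significant, 0)
  expect_lte(sig$percent_significant, 100)
})
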