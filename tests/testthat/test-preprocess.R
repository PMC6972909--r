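test_that("maximum value composite takes the per-cell maximum, skipping NA", {
  ax <- toy_axes(2, 2)
  a <- monthly_raster(ax, 2000L, 4L, array(c(0.41, NA, 0.2, NA), c(1, 2, 2)),
                      "ndvi", validate = FALSE)
  b <- monthly_raster(ax, 2000L, 4L, array(c(0.38, 0.38, NA, NA), c(1, 2, 2)),
                      "ndvi", validate = FALSE)
  got <- mvc_monthly(list(a, b))
  expect_equal(got$values[1, 1, 1], 0.41)
  expect_equal(got$values[1, 2, 1], 0.38)  # missing-skipping
  expect_equal(got$values[1, 1, 2], 0.2)
  expect_true(is.na(got$values[1, 2, 2]))  # both missing stays missing
  # random pairs equal the elementwise max oracle
  set.seed(31)
  r1 <- toy_raster(3, 3, 2000, "ndvi", f = function(t, i, j) runif(1))
  r2 <- toy_raster(3, 3, 2000, "ndvi", f = function(t, i, j) runif(1))
  expect_equal(mvc_monthly(list(r1, r2))$values,
               pmax(r1$values, r2$values))
})

test_that("MVC on generated semimonthly composites recovers the monthly NDVI", {
  cfg <- synth_config(n_lat = 4, n_lon = 4, years = 1981:1990, seed = 5)
  cl <- generate_climate(cfg)
  veg <- generate_ndvi(cl, cfg, semimonthly = TRUE)
  got <- mvc_monthly(veg$ndvi_semimonthly)
  expect_equal(got$values, veg$ndvi$values, tolerance = 1e-12)
})

test_that("QC mask drops abnormal, incomplete and built-up pixels", {
  r <- toy_raster(3, 3, 2000:2001, "ndvi", f = function(t, i, j) 0.4)
  # one abnormal July value
  r$values[time_idx <- 7, 1, 1] <- -0.05
  # one missing growing-season month
  r$values[5, 2, 2] <- NA
  # missing outside the growing season is harmless
  r$values[1, 3, 3] <- NA
  bu <- static_map(r$axes, matrix(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L), 3, 3),
                   "builtup_flag")
  m <- qc_mask(r, bu)
  expect_false(m$valid[1, 1])
  expect_false(m$valid[2, 2])
  expect_false(m$valid[1, 2])  # the built-up pixel despite clean NDVI
  expect_true(m$valid[3, 3])
  expect_true(m$valid[2, 1])
})

test_that("monthly anomalies are centred per calendar month over the base period", {
  # constant series -> all-zero anomalies
  cst <- toy_raster(2, 2, 2000:2003, "precip_mm", f = function(t, i, j) 8)
  a <- monthly_anomalies(cst, c(2000, 2003))
  expect_true(all(abs(a$values) < 1e-12))
  # Julys (1, 3) over a 2-year base -> anomalies (-1, +1)
  two <- toy_raster(1, 1, 2000:2001, "precip_mm",
                    f = function(t, i, j) if (t %% 12 == 7) (t %/% 12) * 2 + 1 else 5)
  a2 <- monthly_anomalies(two, c(2000, 2001))
  expect_equal(a2$values[7, 1, 1], -1)
  expect_equal(a2$values[19, 1, 1], 1)
  # random stack: per-month base-period sums vanish; pre-base years keep the
  # base climatology
  set.seed(32)
  r <- toy_raster(3, 3, 1999:2004, "precip_mm", f = function(t, i, j) runif(1, 0, 50))
  an <- monthly_anomalies(r, c(2000, 2004))
  for (m in 1:12) {
    rows <- which(an$months == m & an$years >= 2000)
    expect_lt(max(abs(apply(an$values[rows, , , drop = FALSE], c(2, 3), sum))),
              1e-9)
  }
  clim_jul <- apply(r$values[r$months == 7 & r$years >= 2000, , ,
                             drop = FALSE], c(2, 3), mean)
  expect_equal(an$values[7, , ], r$values[7, , ] - clim_jul)
  # idempotence under a matching base period
  an2 <- monthly_anomalies(an, c(2000, 2004))
  expect_equal(an2$values, an$values, tolerance = 1e-12)
  expect_error(monthly_anomalies(r, c(2000, 2000)), "2 years")
})

test_that("seasonal aggregation follows the declared month windows", {
  set.seed(33)
  r <- toy_raster(2, 2, 2000:2002, "ndvi", f = function(t, i, j) runif(1))
  sp <- seasonal_aggregate(r, "spring")
  for (k in 1:3) for (i in 1:2) for (j in 1:2)
    expect_equal(sp$values[k, i, j],
                 mean(r$values[r$years == 1999 + k & r$months %in% 4:5, i, j]))
  p <- toy_raster(2, 2, 2000:2002, "precip_mm",
                  f = function(t, i, j) runif(1, 0, 80))
  su <- seasonal_aggregate(p, "summer")
  expect_equal(su$values[2, 1, 2],
               sum(p$values[p$years == 2001 & p$months %in% 6:8, 1, 2]))
  # explicit numbers: spring (0.2, 0.4) -> 0.3; summer precip sums
  tiny <- toy_raster(1, 1, 2000, "ndvi",
                     f = function(t, i, j) c(0, 0, 0, 0.2, 0.4, 0, 0, 0, 0, 0, 0, 0)[t])
  expect_equal(seasonal_aggregate(tiny, "spring")$values[1, 1, 1], 0.3)
  tp <- toy_raster(1, 1, 2000, "precip_mm",
                   f = function(t, i, j) c(0, 0, 0, 0, 0, 10, 20, 30, 0, 0, 0, 0)[t])
  expect_equal(seasonal_aggregate(tp, "summer")$values[1, 1, 1], 60)
  # winter uses Nov-Dec of the previous year; the first year has no winter
  wi <- seasonal_aggregate(p, "winter")
  expect_true(all(is.na(wi$values[1, , ])))
  expect_equal(wi$values[2, 2, 2],
               sum(p$values[(p$years == 2000 & p$months %in% 11:12) |
                            (p$years == 2001 & p$months %in% 1:3), 2, 2]))
  # growing-season mean is the month-count weighted mean of the seasons
  gs <- seasonal_aggregate(r, "growing")
  sm <- seasonal_aggregate(r, "summer"); au <- seasonal_aggregate(r, "autumn")
  expect_equal(gs$values,
               (2 * sp$values + 3 * sm$values + 2 * au$values) / 7,
               tolerance = 1e-12)
})

test_that("accumulation windows follow the lag/cumulation cell semantics", {
  set.seed(34)
  p <- toy_raster(2, 2, 2000:2002, "precip_mm",
                  f = function(t, i, j) runif(1, 0, 60))
  an <- monthly_anomalies(p, c(2000, 2002))
  t0 <- which(an$years == 2002 & an$months == 7)
  # lag 0, cumper 1 is the current month's anomaly
  expect_equal(accumulate_window(an, 0, 1, 7, 2002), an$values[t0, , ])
  # lag 2, cumper 4 sums months 2..5 before the current month
  expect_equal(accumulate_window(an, 2, 4, 7, 2002),
               apply(an$values[(t0 - 5):(t0 - 2), , ], c(2, 3), sum))
  # lag 3, cumper 6 sums months 3..8 before
  expect_equal(accumulate_window(an, 3, 6, 7, 2002),
               apply(an$values[(t0 - 8):(t0 - 3), , ], c(2, 3), sum))
  # additivity: window (l, c) = sum of the c single-month windows
  for (l in 0:2) for (cp in 2:4) {
    acc <- accumulate_window(an, l, cp, 7, 2002)
    parts <- Reduce(`+`, lapply(l:(l + cp - 1),
                                function(k) accumulate_window(an, k, 1, 7, 2002)))
    expect_equal(acc, parts, tolerance = 1e-12)
  }
  expect_error(accumulate_window(an, 3, 6, 2, 2000), "before the start")
})

test_that("area-weighted means use renormalised cos(latitude) weights", {
  r <- toy_raster(3, 3, 2000, "ndvi", f = function(t, i, j) 0.37)
  expect_equal(unname(area_weighted_mean(r)), rep(0.37, 12))
  # two pixels at lat 0 and 60 with values 1 and 0 -> 2/3
  ax <- grid_axes(c(60, 0), 100, cell_size = 60)
  two <- monthly_raster(ax, 2000L, 6L, array(c(0, 1), c(1, 2, 1)), "ndvi")
  expect_equal(unname(area_weighted_mean(two)),
               cos(0) / (cos(0) + cos(pi / 3)), tolerance = 1e-12)
  # random field matches the explicit weighted sum
  set.seed(35)
  rr <- toy_raster(4, 3, 2000, "ndvi", f = function(t, i, j) runif(1))
  w <- matrix(cos(rr$axes$lat * pi / 180), 4, 3)
  for (t in 1:12)
    expect_equal(unname(area_weighted_mean(rr))[t],
                 sum(w * rr$values[t, , ]) / sum(w), tolerance = 1e-12)
  empty <- pixel_mask(rr$axes, matrix(FALSE, 4, 3))
  expect_error(area_weighted_mean(rr, empty), "no valid pixels")
})

test_that("OLS trend matches the normal equations", {
  tr <- ols_trend(c(1, 2, 3), 2000:2002)
  expect_equal(tr$slope, 1)
  expect_equal(tr$r_squared, 1)
  trc <- ols_trend(rep(2, 5), 2000:2004)
  expect_equal(trc$slope, 0)
  expect_equal(trc$r_squared, 0)
  set.seed(36)
  y <- rnorm(34); x <- 1982:2015
  fitted <- ols_trend(y, x)
  slope_ne <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fitted$slope, slope_ne, tolerance = 1e-10)
  expect_error(ols_trend(c(1, 2), 2000:2001), "3 points")
  expect_error(ols_trend(c(1, 2, 3), c(2000, 2000, 2000)), "constant")
})
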