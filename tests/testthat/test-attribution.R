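test_that("binned averages follow the exclusion rule and a loop oracle", {
  # 12 identical values in one bin: mean kept, sd 0
  v12 <- rep(0.5, 12); cov12 <- rep(225, 12)
  prof <- binned_average(v12, cov12, bin_width = 50)
  row <- prof[prof$bin_lo == 200, ]
  expect_equal(row$count, 12L)
  expect_equal(row$mean, 0.5)
  expect_equal(row$sd, 0)
  expect_false(row$excluded)
  # 9 values in a bin are excluded
  prof9 <- binned_average(rep(0.5, 9), rep(225, 9), bin_width = 50)
  expect_true(prof9$excluded[prof9$bin_lo == 200])
  expect_true(is.na(prof9$mean[prof9$bin_lo == 200]))
  # random data against a nested-loop oracle; counts partition the input
  set.seed(71)
  v <- runif(400); cv <- runif(400, 0, 37)
  prof_r <- binned_average(v, cv, bin_width = 5, min_count = 10)
  expect_equal(sum(prof_r$count), 400L)
  for (k in seq_len(nrow(prof_r))) {
    inbin <- v[cv >= prof_r$bin_lo[k] & cv < prof_r$bin_hi[k]]
    expect_equal(prof_r$count[k], length(inbin))
    if (!prof_r$excluded[k]) {
      expect_equal(prof_r$mean[k], mean(inbin), tolerance = 1e-12)
      expect_equal(prof_r$sd[k], stats::sd(inbin), tolerance = 1e-12)
    }
  }
  # pixel order does not matter
  perm <- sample(400)
  expect_equal(binned_average(v[perm], cv[perm], 5), prof_r)
  expect_error(binned_average(v, cv, 0), "positive")
})

test_that("a constructed rise-then-fall gradient peaks in the built-in bin", {
  # r_max rises to a peak around covariate 250 and falls off, mimicking a
  # correlation maximum at intermediate precipitation amounts
  set.seed(72)
  cv <- runif(2000, 0, 800)
  v <- 0.6 - ((cv - 225) / 400)^2 + rnorm(2000, sd = 0.02)
  prof <- binned_average(v, cv, bin_width = 50)
  kept <- prof[!prof$excluded, ]
  expect_equal(kept$bin_lo[which.max(kept$mean)], 200)
})

test_that("ecological zones enumerate observed land-cover x ecoregion pairs", {
  ax <- toy_axes(2, 2)
  lc <- static_map(ax, matrix(c(1L, 1L, 2L, 2L), 2, 2), "landcover_class")
  er <- static_map(ax, matrix(c(1L, 2L, 1L, 2L), 2, 2), "ecoregion_id")
  ez <- eco_zone_intersect(lc, er)
  expect_equal(length(unique(as.vector(ez$values))), 4)
  # a class confined to one ecoregion yields a single zone
  lc2 <- static_map(ax, matrix(c(1L, 1L, 1L, 2L), 2, 2), "landcover_class")
  er2 <- static_map(ax, matrix(c(1L, 1L, 1L, 2L), 2, 2), "ecoregion_id")
  ez2 <- eco_zone_intersect(lc2, er2)
  expect_equal(length(unique(as.vector(ez2$values))), 2)
  # random maps: zone count equals the number of distinct observed pairs
  set.seed(73)
  axr <- toy_axes(10, 10)
  lcv <- matrix(sample(1:4, 100, TRUE), 10, 10)
  erv <- matrix(sample(1:3, 100, TRUE), 10, 10)
  ezr <- eco_zone_intersect(static_map(axr, lcv, "landcover_class"),
                            static_map(axr, erv, "ecoregion_id"))
  expect_equal(length(unique(as.vector(ezr$values))),
               nrow(unique(cbind(as.vector(lcv), as.vector(erv)))))
  # NA in either input propagates
  lcv[1, 1] <- NA
  ezna <- eco_zone_intersect(static_map(axr, lcv, "landcover_class"),
                             static_map(axr, erv, "ecoregion_id"))
  expect_true(is.na(ezna$values[1, 1]))
})

test_that("zone box statistics use interpolated quantiles and the 10-pixel rule", {
  ax <- toy_axes(6, 6)
  zones <- matrix(rep(1:3, each = 12), 6, 6)
  v <- matrix(NA_real_, 6, 6)
  v[zones == 1] <- 0.42              # 12 identical values
  v[zones == 2] <- seq(0, 1, length.out = 12)
  v[zones == 3] <- 0.9
  v[zones == 3][1:3] <- NA           # leaves 9 finite pixels -> omitted
  zs <- zone_boxstats(v, zones, n = 34, n_controls = 2)
  expect_equal(zs$zone_id, c(1L, 2L))
  z1 <- zs[zs$zone_id == 1, ]
  expect_true(all(z1[c("p5", "p25", "p50", "p75", "p95")] == 0.42))
  z2 <- zs[zs$zone_id == 2, ]
  vv <- sort(v[zones == 2])
  q <- stats::quantile(vv, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
  expect_equal(unlist(z2[c("p5", "p25", "p50", "p75", "p95")],
                      use.names = FALSE), q, tolerance = 1e-12)
  expect_true(all(diff(unlist(z2[c("p5", "p25", "p50", "p75", "p95")])) >= 0))
  # significance reference lines round-trip through the t distribution
  cr <- attr(zs, "critical_r")
  expect_equal(r_significance(cr[["alpha_0.05"]], 34, 2)$p_value, 0.05,
               tolerance = 1e-9)
  # permuting the pixels leaves the statistics unchanged
  set.seed(74)
  perm <- sample(36)
  zs_p <- zone_boxstats(matrix(v[perm], 6, 6), matrix(zones[perm], 6, 6),
                        n = 34, n_controls = 2)
  expect_equal(zs_p$p50, zs$p50)
})

test_that("zone temporal medians match a loop oracle and recover seeded peaks", {
  set.seed(75)
  arr <- array(runif(24 * 5 * 5, -0.2, 0.8), c(24, 5, 5))
  zones <- matrix(sample(1:2, 25, TRUE, prob = c(0.6, 0.4)), 5, 5)
  zm <- zone_temporal_medians(arr, zones, min_pixels = 1)
  for (id in 1:2) for (jj in c(1, 13, 24)) {
    want <- stats::median(arr[jj, , ][zones == id])
    expect_equal(zm$median_r[zm$zone_id == id & zm$j == jj], want,
                 tolerance = 1e-12)
  }
  # a single-pixel zone reproduces that pixel's profile
  zones1 <- zones; zones1[2, 2] <- 9L
  zm1 <- zone_temporal_medians(arr, zones1, min_pixels = 1)
  expect_equal(zm1$median_r[zm1$zone_id == 9], arr[, 2, 2])
  # zones under the population threshold are dropped
  zm10 <- zone_temporal_medians(arr, zones1, min_pixels = 10)
  expect_false(9 %in% zm10$zone_id)
  # a zone seeded with one true window peaks at that combination
  w <- small_world()
  cfgz <- synth_config(n_lat = 6, n_lon = 6, seed = 19,
                       lag_field = matrix(1L, 6, 6),
                       cum_field = matrix(2L, 6, 6))
  clz <- generate_climate(cfgz)
  vz <- generate_ndvi(clz, cfgz)
  cube <- monthly_lagcum_correlations(
    monthly_anomalies(vz$ndvi), monthly_anomalies(clz$precip),
    monthly_anomalies(clz$temp), monthly_anomalies(clz$radiation))
  rj <- max_over_months(cube)
  zmz <- zone_temporal_medians(rj, matrix(1L, 6, 6))
  peak <- zmz[which.max(zmz$median_r), ]
  expect_equal(peak$lag, 1)
  expect_equal(peak$cumper, 2)
})

test_that("critical r vanishes as alpha grows and round-trips significance", {
  expect_lt(critical_r(0.999, 34, 2), 0.001)
  for (n in c(14, 34, 120)) {
    rc <- critical_r(0.05, n, 2)
    expect_equal(r_significance(rc, n, 2)$p_value, 0.05, tolerance = 1e-9)
  }
  expect_true(critical_r(0.05, 120, 2) < critical_r(0.05, 34, 2))
})
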