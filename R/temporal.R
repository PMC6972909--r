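#' The 4 x 6 lag/cumulation design
#'
#' Enumerates the 24 combinations of time lag (0–3 months) and precipitation
#' cumulation period (1–6 months) in lag-major order, `j = lag * 6 + cumper`.
#' The window of combination `(lag, cumper)` covers months
#' `lag .. lag + cumper - 1` before the current month (so lag 2, cumper 4 is
#' the "2–5" window).
#'
#' @return A data frame with columns `j`, `lag`, `cumper`, `window` (label).
#' @export
design_combos <- function() {
  g <- expand.grid(cumper = 1:6, lag = 0:3)[, c("lag", "cumper")]
  g$j <- seq_len(nrow(g))
  g$window <- ifelse(g$cumper == 1, as.character(g$lag),
                     paste0(g$lag, "-", g$lag + g$cumper - 1))
  g[, c("j", "lag", "cumper", "window")]
}

flatten_time <- function(raster) {
  v <- raster$values
  dim(v) <- c(dim(v)[1], dim(v)[2] * dim(v)[3])
  v
}

# window sums of a flattened (time x pixel) anomaly matrix for month `i` of
# each analysis year; NA in any contributing month propagates (so that year
# is later dropped pairwise)
window_sum_matrix <- function(flat, raster, years, at_month, lag, cumper) {
  out <- matrix(NA_real_, length(years), ncol(flat))
  for (k in seq_along(years)) {
    t0 <- time_index(raster, years[k], at_month)
    rows <- (t0 - lag - cumper + 1):(t0 - lag)
    if (is.na(t0) || rows[1] < 1)
      stop("accumulation window reaches before the start of the data",
           call. = FALSE)
    out[k, ] <- colSums(flat[rows, , drop = FALSE])
  }
  out
}

#' Monthly lag x cumulation partial-correlation cube
#'
#' For every valid pixel, growing-season month `i` in 4..10 and design
#' combination `j` in 1..24, computes the second-order partial correlation
#' `r[i, j]` between the year-indexed NDVI anomaly series of month `i` and
#' the precipitation anomaly accumulated over window `j`, controlling for
#' temperature and radiation anomalies accumulated over the same window —
#' 168 analyses per pixel. The sample is one value per analysis year;
#' years with a missing value in any of the four series are dropped
#' pairwise for that pixel.
#'
#' @param ndvi_ano,precip_ano,temp_ano,rad_ano Anomaly [monthly_raster()]s on
#'   one grid (see [monthly_anomalies()]); the stacks must extend at least 8
#'   months before April of the first analysis year (the deepest window of
#'   the design).
#' @param mask Optional [pixel_mask()]; invalid pixels yield NA everywhere.
#' @param alpha Significance level for the companion p-values.
#' @param years Analysis years; default every year with a complete growing
#'   season and full window lead (for a 1981–2015 stack: 1982–2015).
#' @param controls_window `"matched"` (controls use the same lag and
#'   cumulation window as precipitation, default) or `"lag0"` (controls
#'   accumulated over the same cumulation period but ending at the current
#'   month).
#' @return An object of class `correlation_cube`: `r` and `p` arrays of
#'   dimension `(7, 24, n_lat, n_lon)`, plus `months`, `combos`, `years`,
#'   `n`, `alpha`, `axes`.
#' @export
monthly_lagcum_correlations <- function(ndvi_ano, precip_ano, temp_ano,
                                        rad_ano, mask = NULL, alpha = 0.05,
                                        years = NULL,
                                        controls_window = c("matched", "lag0")) {
  controls_window <- match.arg(controls_window)
  for (r in list(precip_ano, temp_ano, rad_ano))
    stop_axes(ndvi_ano$axes, r$axes, "anomaly stacks")
  ax <- ndvi_ano$axes
  months <- 4:10
  if (is.null(years)) {
    yrs <- sort(unique(ndvi_ano$years))
    has_gs <- vapply(yrs, function(y)
      !anyNA(time_index(ndvi_ano, rep(y, 7), months)), TRUE)
    first_ok <- vapply(yrs, function(y) {
      t0 <- time_index(precip_ano, y, 4L)
      !is.na(t0) && t0 - 8 >= 1
    }, TRUE)
    years <- yrs[has_gs & first_ok]
  }
  if (length(years) < 7)
    stop("too few analysis years for a meaningful correlation", call. = FALSE)
  combos <- design_combos()
  npix <- ax$n_lat * ax$n_lon
  valid <- if (is.null(mask)) rep(TRUE, npix) else {
    stop_axes(ax, mask$axes, "stack and mask")
    as.vector(mask$valid)
  }
  vcols <- which(valid)
  fN <- flatten_time(ndvi_ano); fP <- flatten_time(precip_ano)
  fT <- flatten_time(temp_ano); fR <- flatten_time(rad_ano)
  rcube <- array(NA_real_, c(7, 24, ax$n_lat, ax$n_lon))
  pcube <- array(NA_real_, c(7, 24, ax$n_lat, ax$n_lon))
  if (length(vcols)) {
    for (im in seq_along(months)) {
      i <- months[im]
      ti <- time_index(ndvi_ano, years, rep(i, length(years)))
      X <- fN[ti, vcols, drop = FALSE]
      for (jj in seq_len(nrow(combos))) {
        l <- combos$lag[jj]; cp <- combos$cumper[jj]
        Y <- window_sum_matrix(fP, precip_ano, years, i, l, cp)[, vcols,
                                                               drop = FALSE]
        cl <- if (controls_window == "matched") l else 0L
        Z1 <- window_sum_matrix(fT, temp_ano, years, i, cl, cp)[, vcols,
                                                                drop = FALSE]
        Z2 <- window_sum_matrix(fR, rad_ano, years, i, cl, cp)[, vcols,
                                                               drop = FALSE]
        res <- parcor2_columns(X, Y, Z1, Z2, alpha = alpha)
        rsl <- rep(NA_real_, npix); psl <- rep(NA_real_, npix)
        rsl[vcols] <- res$r; psl[vcols] <- res$p
        rcube[im, jj, , ] <- rsl
        pcube[im, jj, , ] <- psl
      }
    }
  }
  structure(list(axes = ax, months = months, combos = combos, years = years,
                 n = length(years), alpha = alpha, r = rcube, p = pcube,
                 controls_window = controls_window),
            class = "correlation_cube")
}

#' @export
print.correlation_cube <- function(x, ...) {
  cat(sprintf("correlation_cube: %d months x %d combos x %d x %d grid, %d analysis years (alpha = %g)\n",
              length(x$months), nrow(x$combos), x$axes$n_lat, x$axes$n_lon,
              x$n, x$alpha))
  invisible(x)
}

max_ignore_na <- function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)

#' Per-combination maxima over growing-season months
#'
#' Reduces the cube to 24 per-pixel maps `r_j = max_i r[i, j]`, the signed
#' maximum over the seven growing-season months (missing months are skipped;
#' a pixel-combination is missing only if all seven months are). The month
#' attaining the maximum and its p-value are kept alongside.
#'
#' @param cube A `correlation_cube`.
#' @return An object of class `rj_maps`: arrays `r_j`, `p_at_max`,
#'   `month_at_max` of dimension `(24, n_lat, n_lon)`.
#' @export
max_over_months <- function(cube) {
  stopifnot(inherits(cube, "correlation_cube"))
  d <- dim(cube$r)
  rj <- array(NA_real_, d[2:4]); pj <- array(NA_real_, d[2:4])
  mj <- array(NA_integer_, d[2:4])
  for (jj in seq_len(d[2])) {
    sl <- cube$r[, jj, , , drop = TRUE]
    dim(sl) <- c(d[1], d[3] * d[4])
    psl <- cube$p[, jj, , , drop = TRUE]
    dim(psl) <- c(d[1], d[3] * d[4])
    any_ok <- colSums(!is.na(sl)) > 0
    im <- rep(NA_integer_, ncol(sl))
    im[any_ok] <- apply(sl[, any_ok, drop = FALSE], 2, which.max)
    sel <- cbind(im, seq_along(im))
    rj[jj, , ] <- sl[sel]
    pj[jj, , ] <- psl[sel]
    mj[jj, , ] <- cube$months[im]
  }
  structure(list(axes = cube$axes, combos = cube$combos, months = cube$months,
                 n = cube$n, alpha = cube$alpha,
                 r_j = rj, p_at_max = pj, month_at_max = mj),
            class = "rj_maps")
}

#' Per-pixel maximum over the 24 combinations
#'
#' `r_max = max_j r_j`, with argmax metadata (best combination index, lag and
#' cumulation period). Ties are broken towards the smallest lag, then the
#' smallest cumulation period. A pixel is flagged `any_significant` if at
#' least one of its 168 monthly analyses is significant at the cube's
#' `alpha`.
#'
#' @param rj An `rj_maps` object from [max_over_months()].
#' @param cube The originating `correlation_cube` (for the significance
#'   flags); optional — without it `any_significant` is based on the
#'   p-values at the per-combination maxima.
#' @return An object of class `correlation_summary` with matrices `r_max`,
#'   `best_j`, `best_lag`, `best_cumper`, `any_significant`.
#' @export
max_over_combos <- function(rj, cube = NULL) {
  stopifnot(inherits(rj, "rj_maps"))
  d <- dim(rj$r_j)
  m <- rj$r_j; dim(m) <- c(d[1], d[2] * d[3])
  any_ok <- colSums(!is.na(m)) > 0
  bj <- rep(NA_integer_, ncol(m))
  # combos are in lag-major ascending order, so the first maximum realises
  # the smallest-lag-then-smallest-cumper tie rule
  bj[any_ok] <- apply(m[, any_ok, drop = FALSE], 2, which.max)
  rmax <- m[cbind(bj, seq_along(bj))]
  if (!is.null(cube)) {
    pc <- cube$p; dim(pc) <- c(dim(pc)[1] * dim(pc)[2], d[2] * d[3])
    anysig <- colSums(pc < rj$alpha, na.rm = TRUE) > 0
  } else {
    pm <- rj$p_at_max; dim(pm) <- c(d[1], d[2] * d[3])
    anysig <- colSums(pm < rj$alpha, na.rm = TRUE) > 0
  }
  anysig[!any_ok] <- NA
  shape <- function(v) { dim(v) <- d[2:3]; v }
  structure(list(axes = rj$axes, combos = rj$combos, n = rj$n,
                 alpha = rj$alpha,
                 r_max = shape(rmax), best_j = shape(bj),
                 best_lag = shape(rj$combos$lag[bj]),
                 best_cumper = shape(rj$combos$cumper[bj]),
                 any_significant = shape(anysig)),
            class = "correlation_summary")
}

#' Best time lag among 1-month-cumulation analyses
#'
#' Restricts the cube to the four combinations with a 1-month cumulation
#' period and reports, per pixel, the lag whose `r_j` is largest, plus the
#' percentage share of each lag among pixels with at least one significant
#' analysis.
#'
#' @param rj An `rj_maps` object.
#' @param summary Optional `correlation_summary` supplying the
#'   any-significant selection for the share table (defaults to p-values at
#'   the per-combination maxima).
#' @return A list: `lag_map` (matrix of best lags 0–3) and `shares` (data
#'   frame `lag`, `count`, `percent`; percentages sum to 100 over pixels in
#'   the selection).
#' @export
best_lag_map <- function(rj, summary = NULL) {
  stopifnot(inherits(rj, "rj_maps"))
  sel <- which(rj$combos$cumper == 1)
  sub <- rj$r_j[sel, , , drop = FALSE]
  d <- dim(sub); dim(sub) <- c(d[1], d[2] * d[3])
  any_ok <- colSums(!is.na(sub)) > 0
  bi <- rep(NA_integer_, ncol(sub))
  bi[any_ok] <- apply(sub[, any_ok, drop = FALSE], 2, which.max)
  lag_map <- matrix(rj$combos$lag[sel][bi], d[2], d[3])
  shares <- share_table(lag_map, rj, summary, levels = 0:3, name = "lag")
  list(lag_map = lag_map, shares = shares)
}

#' Best cumulation period among no-lag analyses
#'
#' Restricts the cube to the six lag-0 combinations and reports, per pixel,
#' the cumulation period whose `r_j` is largest, plus percentage shares over
#' pixels with at least one significant analysis.
#'
#' @inheritParams best_lag_map
#' @return A list: `cum_map` and `shares` (`cumper`, `count`, `percent`).
#' @export
best_cum_map <- function(rj, summary = NULL) {
  stopifnot(inherits(rj, "rj_maps"))
  sel <- which(rj$combos$lag == 0)
  sub <- rj$r_j[sel, , , drop = FALSE]
  d <- dim(sub); dim(sub) <- c(d[1], d[2] * d[3])
  any_ok <- colSums(!is.na(sub)) > 0
  bi <- rep(NA_integer_, ncol(sub))
  bi[any_ok] <- apply(sub[, any_ok, drop = FALSE], 2, which.max)
  cum_map <- matrix(rj$combos$cumper[sel][bi], d[2], d[3])
  shares <- share_table(cum_map, rj, summary, levels = 1:6, name = "cumper")
  list(cum_map = cum_map, shares = shares)
}

share_table <- function(value_map, rj, summary, levels, name) {
  insel <- if (!is.null(summary)) summary$any_significant else {
    d <- dim(rj$p_at_max)
    pm <- rj$p_at_max; dim(pm) <- c(d[1], d[2] * d[3])
    m <- colSums(pm < rj$alpha, na.rm = TRUE) > 0
    dim(m) <- d[2:3]; m
  }
  vals <- value_map[which(insel & !is.na(value_map))]
  counts <- vapply(levels, function(l) sum(vals == l), 1L)
  out <- data.frame(level = levels, count = counts,
                    percent = if (sum(counts) > 0) 100 * counts / sum(counts)
                              else rep(NA_real_, length(levels)))
  names(out)[1] <- name
  out
}

#' Fraction of valid pixels with a significant correlation
#'
#' The share (in percent) of valid pixels for which at least one of the 168
#' monthly lag/cumulation analyses is significant at `alpha` — the
#' proportion of the landscape whose vegetation shows a detectable
#' precipitation response.
#'
#' @param cube A `correlation_cube`.
#' @param mask Optional [pixel_mask()] restricting the denominator.
#' @param alpha Significance level (default the cube's).
#' @return A list: `percent_significant`, `n_valid`, `n_significant`, and
#'   the logical `any_significant` matrix.
#' @export
significance_summary <- function(cube, mask = NULL, alpha = NULL) {
  stopifnot(inherits(cube, "correlation_cube"))
  if (is.null(alpha)) alpha <- cube$alpha
  d <- dim(cube$p)
  pc <- cube$p; dim(pc) <- c(d[1] * d[2], d[3] * d[4])
  computed <- colSums(!is.na(pc)) > 0
  anysig <- colSums(pc < alpha, na.rm = TRUE) > 0
  valid <- computed
  if (!is.null(mask)) valid <- valid & as.vector(mask$valid)
  n_valid <- sum(valid)
  n_sig <- sum(anysig & valid)
  m <- anysig & valid; dim(m) <- d[3:4]
  list(percent_significant = if (n_valid > 0) 100 * n_sig / n_valid else NA_real_,
       n_valid = n_valid, n_significant = n_sig, any_significant = m)
}
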