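#' Seasonal correlation modes
#'
#' The four temporal configurations relating a precipitation window to the
#' NDVI season: `Ra0` (same season), `Ra-1` (previous season), `Ra(-1,0)`
#' (previous plus current season), `Ra(-2,-1)` (the two previous seasons).
#' Season arithmetic follows the winter (Nov–Mar) -> spring -> summer ->
#' autumn sequence with year carry, so e.g. spring's previous season is the
#' winter ending in March of the same year, and spring's previous two
#' seasons are the prior year's autumn plus that winter.
#'
#' @return A data frame with columns `mode` and `offsets` (list column of
#'   season offsets relative to the NDVI season; 0 = same season).
#' @export
seasonal_modes <- function() {
  data.frame(mode = c("Ra0", "Ra-1", "Ra(-1,0)", "Ra(-2,-1)"),
             offsets = I(list(0L, -1L, c(-1L, 0L), c(-2L, -1L))),
             stringsAsFactors = FALSE)
}

# season sequence used for previous-season arithmetic
.season_seq <- c("winter", "spring", "summer", "autumn")

# resolve (season, year, offset) -> (season, year)
season_shift <- function(season, offset) {
  i <- match(season, .season_seq) - 1L + offset
  list(season = .season_seq[(i %% 4L) + 1L], year_carry = i %/% 4L)
}

#' Per-year series for a seasonal correlation mode
#'
#' Aggregates a monthly stack over the precipitation window of a mode
#' relative to an NDVI season: each season in the window is aggregated with
#' [seasonal_aggregate()] (sum for precipitation-like variables, mean for
#' NDVI) and multi-season windows are summed season by season, so the
#' `Ra(-1,0)` series equals the `Ra-1` plus `Ra0` series year by year for
#' summed variables.
#'
#' @param stack A [monthly_raster()] (raw or anomaly).
#' @param season NDVI season: `"spring"`, `"summer"` or `"autumn"`.
#' @param mode One of `"Ra0"`, `"Ra-1"`, `"Ra(-1,0)"`, `"Ra(-2,-1)"`.
#' @param years Analysis years.
#' @param statistic Passed to [seasonal_aggregate()] (default by variable).
#' @return A `yearly_raster`; years whose window reaches before the stack
#'   are missing.
#' @export
seasonal_series <- function(stack, season, mode, years = NULL,
                            statistic = NULL) {
  md <- seasonal_modes()
  if (!mode %in% md$mode) stop("unknown mode '", mode, "'", call. = FALSE)
  if (!season %in% c("spring", "summer", "autumn"))
    stop("season must be spring, summer or autumn", call. = FALSE)
  offsets <- md$offsets[[match(mode, md$mode)]]
  if (is.null(years)) years <- sort(unique(stack$years))
  total <- NULL
  for (off in offsets) {
    sh <- season_shift(season, off)
    agg <- seasonal_aggregate(stack, sh$season, statistic = statistic,
                              years = years + sh$year_carry)
    total <- if (is.null(total)) agg$values else total + agg$values
  }
  yearly_raster(stack$axes, years, total, stack$variable, stack$units)
}

#' Seasonal partial correlations between NDVI and precipitation anomalies
#'
#' For each NDVI season (spring, summer, autumn) and each of the four
#' seasonal modes, computes the per-pixel second-order partial correlation
#' between the seasonal NDVI anomaly and the precipitation anomaly
#' accumulated over the mode's window, controlling for temperature and
#' radiation anomalies accumulated over the same window. Anomalies are
#' anomalies-of-aggregates: each seasonal (window) aggregate has its
#' base-period mean removed before correlating.
#'
#' @param ndvi,precip,temp,rad [monthly_raster()]s on one grid (raw values;
#'   anomaly stacks are also accepted since the aggregate is re-centred).
#' @param mask Optional [pixel_mask()].
#' @param alpha Significance level.
#' @param years Analysis years (default: all years with every required
#'   season available, typically the stack years minus the lead year).
#' @param base_period Years over which the aggregate climatology is taken
#'   (default the analysis years).
#' @return An object of class `seasonal_correlation_set`: arrays `r`, `p` of
#'   dimension `(3, 4, n_lat, n_lon)` with season and mode dimnames.
#' @export
seasonal_parcorr <- function(ndvi, precip, temp, rad, mask = NULL,
                             alpha = 0.05, years = NULL, base_period = NULL) {
  for (r in list(precip, temp, rad)) stop_axes(ndvi$axes, r$axes, "stacks")
  ax <- ndvi$axes
  seasons <- c("spring", "summer", "autumn")
  modes <- seasonal_modes()$mode
  if (is.null(years)) {
    yrs <- sort(unique(ndvi$years))
    # deepest window: autumn's two previous seasons reach back to November
    # two years prior only for spring; requiring the previous year suffices
    years <- yrs[yrs > min(yrs)]
  }
  if (length(years) < 6) stop("too few analysis years", call. = FALSE)
  npix <- ax$n_lat * ax$n_lon
  valid <- if (is.null(mask)) rep(TRUE, npix) else as.vector(mask$valid)
  vcols <- which(valid)
  rarr <- array(NA_real_, c(3, 4, ax$n_lat, ax$n_lon),
                dimnames = list(seasons, modes, NULL, NULL))
  parr <- rarr
  centre <- function(yr) {
    v <- yr$values; dim(v) <- c(dim(v)[1], npix)
    base <- if (is.null(base_period)) seq_len(nrow(v)) else
      which(yr$years %in% base_period[1]:base_period[2])
    mu <- colMeans(v[base, , drop = FALSE])
    sweep(v, 2, mu)
  }
  for (s in seasons) {
    nd <- seasonal_aggregate(ndvi, s, statistic = "mean", years = years)
    X <- centre(nd)[, vcols, drop = FALSE]
    for (m in modes) {
      Y <- centre(seasonal_series(precip, s, m, years, statistic = "sum"))
      Z1 <- centre(seasonal_series(temp, s, m, years, statistic = "sum"))
      Z2 <- centre(seasonal_series(rad, s, m, years, statistic = "sum"))
      res <- parcor2_columns(X, Y[, vcols, drop = FALSE],
                             Z1[, vcols, drop = FALSE],
                             Z2[, vcols, drop = FALSE], alpha = alpha)
      rsl <- rep(NA_real_, npix); psl <- rep(NA_real_, npix)
      rsl[vcols] <- res$r; psl[vcols] <- res$p
      rarr[s, m, , ] <- rsl
      parr[s, m, , ] <- psl
    }
  }
  structure(list(axes = ax, seasons = seasons, modes = modes, years = years,
                 n = length(years), alpha = alpha, r = rarr, p = parr),
            class = "seasonal_correlation_set")
}

#' @export
print.seasonal_correlation_set <- function(x, ...) {
  cat(sprintf("seasonal_correlation_set: 3 seasons x 4 modes on a %d x %d grid, %d years\n",
              x$axes$n_lat, x$axes$n_lon, x$n))
  invisible(x)
}
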