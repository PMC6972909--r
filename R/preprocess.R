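#' Season partition of the calendar year
#'
#' Growing season April–October, subdivided into spring (April–May), summer
#' (June–August) and autumn (September–October). The non-growing "winter"
#' season is November–March; it crosses the year boundary and is labelled by
#' the year of its January–March part, so the four seasons partition the
#' twelve months and `growing = spring + summer + autumn`.
#'
#' @return Named list of integer month vectors.
#' @export
season_partition <- function() {
  list(growing = 4:10, spring = 4:5, summer = 6:8, autumn = 9:10,
       winter = c(11L, 12L, 1L, 2L, 3L))
}

#' Maximum value composite of sub-monthly NDVI
#'
#' Collapses paired (or more) sub-monthly composites into one monthly value by
#' taking the per-cell maximum, the standard technique for suppressing
#' atmospheric noise in AVHRR-era NDVI. A cell is missing only if all of its
#' composites are missing.
#'
#' @param composites A list of [monthly_raster()] objects on one grid and one
#'   time axis, one entry per within-month composite.
#' @return A [monthly_raster()] of the composited variable.
#' @export
mvc_monthly <- function(composites) {
  stopifnot(length(composites) >= 1,
            all(vapply(composites, inherits, TRUE, "monthly_raster")))
  base <- composites[[1]]
  out <- base$values
  for (r in composites[-1]) {
    stop_axes(base$axes, r$axes, "composites")
    if (!identical(base$years, r$years) || !identical(base$months, r$months))
      stop("composites differ in time axis", call. = FALSE)
    out <- pmax(out, r$values, na.rm = TRUE)
  }
  monthly_raster(base$axes, base$years, base$months, out, base$variable,
                 units = base$units, validate = FALSE)
}

#' Quality-control pixel mask
#'
#' A pixel is invalid if it is flagged built-up, if any growing-season NDVI
#' value satisfies the abnormal-value rule (default: NDVI <= 0, the signature
#' of contamination around water bodies and mountains), or if any
#' growing-season month in the record is missing.
#'
#' @param ndvi A [monthly_raster()] of NDVI.
#' @param builtup Optional [static_map()] of kind `"builtup_flag"` (nonzero =
#'   built-up).
#' @param abnormal_rule Predicate on values; cells where it returns `TRUE`
#'   during the screened months poison the pixel. Default `function(v) v <= 0`.
#' @param months Months screened (default the growing season, 4:10).
#' @return A [pixel_mask()].
#' @export
qc_mask <- function(ndvi, builtup = NULL, abnormal_rule = function(v) v <= 0,
                    months = 4:10) {
  stopifnot(inherits(ndvi, "monthly_raster"))
  sel <- ndvi$months %in% months
  v <- ndvi$values[sel, , , drop = FALSE]
  bad <- apply(is.na(v), c(2, 3), any)
  abn <- abnormal_rule(v)
  abn[is.na(abn)] <- FALSE
  bad <- bad | apply(abn, c(2, 3), any)
  if (!is.null(builtup)) {
    stop_axes(ndvi$axes, builtup$axes, "ndvi and builtup map")
    bad <- bad | (!is.na(builtup$values) & builtup$values != 0)
  }
  pixel_mask(ndvi$axes, !bad)
}

#' Monthly anomalies relative to a base-period climatology
#'
#' Subtracts, for every cell, the mean of its calendar month over the base
#' period (default 1982–2015). Anomalies are defined for all months in the
#' stack, including months before the base period (a 1981 lead year exists
#' only to feed lagged accumulation windows and still uses the 1982–2015
#' climatology). Per pixel and calendar month the base-period anomalies sum
#' to zero by construction.
#'
#' @param stack A [monthly_raster()].
#' @param base_period Integer `c(first_year, last_year)`; must span at least
#'   two years and lie within the stack.
#' @return A [monthly_raster()] of anomalies (class also `anomaly_raster`);
#'   the `base_period` is attached as a field.
#' @export
monthly_anomalies <- function(stack, base_period = c(1982L, 2015L)) {
  stopifnot(inherits(stack, "monthly_raster"))
  b0 <- base_period[1]; b1 <- base_period[2]
  if (b1 - b0 + 1 < 2) stop("base period must span at least 2 years", call. = FALSE)
  if (b0 < min(stack$years) || b1 > max(stack$years))
    stop("base period outside the stack's years", call. = FALSE)
  out <- stack$values
  for (m in sort(unique(stack$months))) {
    in_base <- stack$months == m & stack$years >= b0 & stack$years <= b1
    if (!any(in_base))
      stop("no base-period slices for month ", m, call. = FALSE)
    clim <- colMeans(stack$values[in_base, , , drop = FALSE], dims = 1)
    rows <- which(stack$months == m)
    for (t in rows) out[t, , ] <- stack$values[t, , ] - clim
  }
  r <- monthly_raster(stack$axes, stack$years, stack$months, out,
                      stack$variable, units = stack$units, validate = FALSE)
  r$base_period <- c(b0, b1)
  class(r) <- c("anomaly_raster", class(r))
  r
}

#' Yearly raster container
#'
#' One value per (year, lat, lon); the product of seasonal aggregation.
#' @keywords internal
yearly_raster <- function(axes, years, values, variable, units) {
  structure(list(axes = axes, years = as.integer(years), values = values,
                 variable = variable, units = units),
            class = "yearly_raster")
}

#' Aggregate a monthly stack to one value per year over a season window
#'
#' NDVI-like indices average over the season; precipitation-like amounts sum.
#' Winter (November–March) for year `y` uses November–December of year
#' `y - 1` plus January–March of `y`; the first year of a stack therefore has
#' no winter value. A cell-year is missing if any contributing month is
#' missing.
#'
#' @param stack A [monthly_raster()] (or anomaly raster).
#' @param season One of `"growing"`, `"spring"`, `"summer"`, `"autumn"`,
#'   `"winter"`, or an integer vector of months (interpreted as a same-year
#'   window unless it matches the winter pattern).
#' @param statistic `"mean"` or `"sum"`; default `"sum"` for `precip_mm`,
#'   `"mean"` otherwise.
#' @param years Years to aggregate (default all years in the stack).
#' @return A `yearly_raster` with values `(n_years, n_lat, n_lon)`.
#' @export
seasonal_aggregate <- function(stack, season, statistic = NULL, years = NULL) {
  stopifnot(inherits(stack, "monthly_raster"))
  if (is.character(season)) {
    sp <- season_partition()
    if (!season %in% names(sp)) stop("unknown season '", season, "'", call. = FALSE)
    months <- sp[[season]]
  } else months <- as.integer(season)
  if (is.null(statistic))
    statistic <- if (stack$variable == "precip_mm") "sum" else "mean"
  statistic <- match.arg(statistic, c("mean", "sum"))
  if (is.null(years)) years <- sort(unique(stack$years))
  crosses <- any(diff(months) < 0)  # e.g. 11,12,1,2,3
  out <- array(NA_real_, c(length(years), stack$axes$n_lat, stack$axes$n_lon))
  for (k in seq_along(years)) {
    y <- years[k]
    yr <- if (crosses) ifelse(months >= months[1], y - 1L, y) else rep(y, length(months))
    ti <- time_index(stack, yr, months)
    if (anyNA(ti)) next
    sl <- stack$values[ti, , , drop = FALSE]
    agg <- colSums(sl, dims = 1)            # NA-propagating on purpose
    if (statistic == "mean") agg <- agg / length(months)
    out[k, , ] <- agg
  }
  yearly_raster(stack$axes, years, out, stack$variable, stack$units)
}

#' Accumulated precipitation anomaly over a lag/cumulation window
#'
#' Sums anomalies over the `cumper` consecutive months ending `lag` months
#' before (for `lag = 0`, ending at and including) the target month. The
#' window for lag `l` and cumulation period `c` covers months
#' `l, l+1, ..., l+c-1` before the current month, so e.g. lag 2 with a
#' 4-month cumulation period sums months 2–5 before the target.
#'
#' @param ano An anomaly [monthly_raster()].
#' @param lag Time lag in months, 0–3 in the standard design.
#' @param cumper Cumulation period in months, 1–6 in the standard design.
#' @param at_month Calendar month of the target.
#' @param at_year Year (scalar) or years (vector) of the target.
#' @return If `at_year` is scalar, a `(n_lat, n_lon)` matrix; otherwise an
#'   array `(n_years, n_lat, n_lon)`.
#' @export
accumulate_window <- function(ano, lag, cumper, at_month, at_year) {
  stopifnot(inherits(ano, "monthly_raster"), lag >= 0, cumper >= 1)
  scal <- length(at_year) == 1
  out <- array(NA_real_, c(length(at_year), ano$axes$n_lat, ano$axes$n_lon))
  for (k in seq_along(at_year)) {
    t0 <- time_index(ano, at_year[k], at_month)
    if (is.na(t0)) stop("target month not in the stack", call. = FALSE)
    rows <- (t0 - lag - cumper + 1):(t0 - lag)
    if (rows[1] < 1)
      stop("accumulation window reaches before the start of the data",
           call. = FALSE)
    out[k, , ] <- colSums(ano$values[rows, , , drop = FALSE], dims = 1)
  }
  if (scal) out[1, , ] else out
}

#' Area-weighted spatial mean series
#'
#' Averages a monthly or yearly raster over valid pixels with
#' `cos(latitude)` weights, renormalised over the pixels that are valid and
#' non-missing at each time step.
#'
#' @param stack A [monthly_raster()] or `yearly_raster`.
#' @param mask Optional [pixel_mask()]; defaults to all pixels.
#' @return Numeric series, one value per time step (named by year or
#'   year-month).
#' @export
area_weighted_mean <- function(stack, mask = NULL) {
  ax <- stack$axes
  valid <- if (is.null(mask)) matrix(TRUE, ax$n_lat, ax$n_lon) else {
    stop_axes(ax, mask$axes, "stack and mask")
    mask$valid
  }
  if (!any(valid)) stop("no valid pixels", call. = FALSE)
  w <- matrix(cos(ax$lat * pi / 180), ax$n_lat, ax$n_lon)
  w[!valid] <- 0
  nt <- dim(stack$values)[1]
  out <- numeric(nt)
  for (t in seq_len(nt)) {
    sl <- stack$values[t, , ]
    wt <- w * !is.na(sl)
    sw <- sum(wt)
    out[t] <- if (sw > 0) sum(wt * sl, na.rm = TRUE) / sw else NA_real_
  }
  names(out) <- if (!is.null(stack$months))
    sprintf("%d-%02d", stack$years, stack$months) else as.character(stack$years)
  out
}

#' Ordinary least-squares trend of a yearly series
#'
#' Fits `value ~ year` by OLS and reports the slope (units per year),
#' intercept, R-squared and the two-sided t-test p-value of the slope.
#'
#' @param series Numeric yearly values.
#' @param years Calendar years (default: taken from `names(series)` or
#'   consecutive integers).
#' @return A list of class `trend_result` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
ols_trend <- function(series, years = NULL) {
  if (is.null(years)) {
    years <- suppressWarnings(as.numeric(names(series)))
    if (is.null(names(series)) || anyNA(years)) years <- seq_along(series)
  }
  keep <- !is.na(series) & !is.na(years)
  y <- series[keep]; x <- years[keep]
  if (length(y) < 3) stop("need at least 3 points", call. = FALSE)
  if (stats::var(x) == 0) stop("constant time axis", call. = FALSE)
  if (stats::var(y) == 0)
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = 1, n = length(y)),
                     class = "trend_result"))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)["x"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients["x", "Pr(>|t|)"],
                 n = length(y)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("OLS trend: slope %.6g per year, R^2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}
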