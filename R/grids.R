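#' Grid axes for a regular lat/lon raster
#'
#' Cell-centre registered regular grid. Latitude runs north to south
#' (descending, north at row index 1) by convention; this is validated and
#' recorded so every raster in a pipeline shares one orientation.
#'
#' @param lat_centers Numeric vector of cell-centre latitudes (degrees north),
#'   strictly monotone, uniformly spaced.
#' @param lon_centers Numeric vector of cell-centre longitudes (degrees east),
#'   strictly monotone, uniformly spaced.
#' @param cell_size Cell size in degrees (default 0.5). Must match the axis
#'   spacing where more than one centre is given.
#' @return An object of class `grid_axes`.
#' @examples
#' ax <- grid_axes(seq(49.75, 45.25, by = -0.5), seq(100.25, 104.75, by = 0.5))
#' ax$n_lat
#' @export
grid_axes <- function(lat_centers, lon_centers, cell_size = 0.5) {
  lat_centers <- as.numeric(lat_centers)
  lon_centers <- as.numeric(lon_centers)
  if (any(lat_centers < -90 | lat_centers > 90))
    stop("latitudes must lie in [-90, 90]", call. = FALSE)
  if (any(lon_centers < -180 | lon_centers >= 360))
    stop("longitudes must lie in [-180, 360)", call. = FALSE)
  check_uniform <- function(x, nm) {
    if (length(x) >= 2) {
      d <- diff(x)
      if (any(abs(abs(d) - abs(d[1])) > 1e-9))
        stop(nm, " centres are not uniformly spaced", call. = FALSE)
      if (any(sign(d) != sign(d[1])) || d[1] == 0)
        stop(nm, " centres must be strictly monotone", call. = FALSE)
      if (abs(abs(d[1]) - cell_size) > 1e-9)
        stop(nm, " spacing does not match cell_size", call. = FALSE)
    }
  }
  check_uniform(lat_centers, "latitude")
  check_uniform(lon_centers, "longitude")
  structure(
    list(lat = lat_centers, lon = lon_centers, cell_size = cell_size,
         n_lat = length(lat_centers), n_lon = length(lon_centers)),
    class = "grid_axes")
}

#' @export
print.grid_axes <- function(x, ...) {
  cat(sprintf("grid_axes: %d x %d cells of %g deg, lat [%g, %g], lon [%g, %g]\n",
              x$n_lat, x$n_lon, x$cell_size,
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

axes_equal <- function(a, b, tol = 1e-9) {
  a$n_lat == b$n_lat && a$n_lon == b$n_lon &&
    abs(a$cell_size - b$cell_size) < tol &&
    all(abs(a$lat - b$lat) < tol) && all(abs(a$lon - b$lon) < tol)
}

stop_axes <- function(a, b, what = "objects") {
  if (!axes_equal(a, b)) stop(what, " are on different grids", call. = FALSE)
  invisible(TRUE)
}

# known variables and canonical units
.vp_variables <- c(ndvi = "1", precip_mm = "mm", temp_C = "degC",
                   radiation_MJ_m2_d = "MJ m-2 d-1", wet_days = "1",
                   sunshine_h = "h")

days_in_month <- function(year, month) {
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  d[month == 2 & leap] <- 29
  d
}

#' Monthly raster stack
#'
#' A (time, lat, lon) stack of one variable on a [grid_axes()] grid with a
#' contiguous monthly calendar. Missing cells are `NA` in `values`; there is
#' no magic fill value inside the package.
#'
#' @param axes A [grid_axes()] object.
#' @param years,months Integer vectors of equal length giving the (year, month)
#'   of each time slice, strictly increasing and contiguous (no skipped
#'   months).
#' @param values Numeric array with dim `(n_time, n_lat, n_lon)`.
#' @param variable One of `"ndvi"`, `"precip_mm"`, `"temp_C"`,
#'   `"radiation_MJ_m2_d"`, `"wet_days"`, `"sunshine_h"`.
#' @param units Units string; defaults to the canonical units of `variable`.
#' @param validate Check range invariants (NDVI in \[-1, 1\], precipitation
#'   non-negative, wet days within the month length).
#' @return An object of class `monthly_raster`.
#' @export
monthly_raster <- function(axes, years, months, values, variable,
                           units = NULL, validate = TRUE) {
  stopifnot(inherits(axes, "grid_axes"))
  years <- as.integer(years); months <- as.integer(months)
  nt <- length(years)
  if (length(months) != nt) stop("years and months differ in length", call. = FALSE)
  if (nt == 0) stop("empty time axis", call. = FALSE)
  idx <- years * 12L + (months - 1L)
  if (nt > 1 && any(diff(idx) != 1L))
    stop("time axis is not contiguous monthly (skipped or repeated months)",
         call. = FALSE)
  if (any(months < 1L | months > 12L)) stop("months must be 1..12", call. = FALSE)
  if (!is.array(values) || length(dim(values)) != 3)
    stop("values must be a 3-d array (time, lat, lon)", call. = FALSE)
  if (!all(dim(values) == c(nt, axes$n_lat, axes$n_lon)))
    stop("values dimensions do not match time/axes", call. = FALSE)
  if (!variable %in% names(.vp_variables))
    stop("unknown variable '", variable, "'", call. = FALSE)
  if (is.null(units)) units <- unname(.vp_variables[variable])
  if (validate) {
    v <- values[!is.na(values)]
    if (variable == "ndvi" && length(v) && (min(v) < -1 || max(v) > 1))
      stop("NDVI values outside [-1, 1]", call. = FALSE)
    if (variable %in% c("precip_mm", "wet_days", "sunshine_h") &&
        length(v) && min(v) < 0)
      stop(variable, " must be non-negative", call. = FALSE)
    if (variable == "wet_days") {
      dim_ok <- sweep(values, 1, days_in_month(years, months), "<=")
      if (any(!dim_ok[!is.na(values)]))
        stop("wet_days exceed days in month", call. = FALSE)
    }
  }
  structure(list(axes = axes, years = years, months = months,
                 values = values, variable = variable, units = units),
            class = "monthly_raster")
}

#' @export
print.monthly_raster <- function(x, ...) {
  cat(sprintf("monthly_raster '%s' [%s]: %d months (%d-%02d .. %d-%02d), %d x %d grid, %.1f%% missing\n",
              x$variable, x$units, length(x$years),
              x$years[1], x$months[1],
              x$years[length(x$years)], x$months[length(x$months)],
              x$axes$n_lat, x$axes$n_lon,
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Missing-value mask of a monthly raster
#'
#' @param raster A [monthly_raster()].
#' @return Logical array, `TRUE` where the value is missing.
#' @export
missing_mask <- function(raster) is.na(raster$values)

# index of (year, month) slices in a raster; NA where absent
time_index <- function(raster, years, months) {
  match(years * 12L + (months - 1L),
        raster$years * 12L + (raster$months - 1L))
}

#' Static (single-layer) map
#'
#' @param axes A [grid_axes()] object.
#' @param values Numeric or integer matrix `(n_lat, n_lon)`; categorical kinds
#'   use integer codes.
#' @param kind One of `"elevation_m"`, `"cti"`, `"sbd_g_cm3"`, `"pawc_mm"`,
#'   `"landcover_class"`, `"ecoregion_id"`, `"ecozone_id"`, `"builtup_flag"`.
#' @param code_table Optional data frame `(code, label)` for categorical kinds.
#' @return An object of class `static_map`.
#' @export
static_map <- function(axes, values, kind, code_table = NULL) {
  stopifnot(inherits(axes, "grid_axes"))
  kinds <- c("elevation_m", "cti", "sbd_g_cm3", "pawc_mm",
             "landcover_class", "ecoregion_id", "ecozone_id", "builtup_flag")
  if (!kind %in% kinds) stop("unknown static map kind '", kind, "'", call. = FALSE)
  if (!is.matrix(values) || !all(dim(values) == c(axes$n_lat, axes$n_lon)))
    stop("values must be an (n_lat, n_lon) matrix", call. = FALSE)
  categorical <- kind %in% c("landcover_class", "ecoregion_id", "ecozone_id",
                             "builtup_flag")
  if (categorical) storage.mode(values) <- "integer"
  structure(list(axes = axes, values = values, kind = kind,
                 categorical = categorical, code_table = code_table),
            class = "static_map")
}

#' Pixel validity mask
#'
#' @param axes A [grid_axes()] object.
#' @param valid Logical matrix `(n_lat, n_lon)`.
#' @return An object of class `pixel_mask`.
#' @export
pixel_mask <- function(axes, valid) {
  stopifnot(inherits(axes, "grid_axes"))
  if (!is.matrix(valid) || !is.logical(valid) ||
      !all(dim(valid) == c(axes$n_lat, axes$n_lon)))
    stop("valid must be a logical (n_lat, n_lon) matrix", call. = FALSE)
  valid[is.na(valid)] <- FALSE
  structure(list(axes = axes, valid = valid), class = "pixel_mask")
}

#' Combine pixel masks by logical AND
#'
#' A pixel is valid in the result only if it is valid in every input mask.
#'
#' @param masks A list of [pixel_mask()] objects on identical axes.
#' @return A [pixel_mask()].
#' @export
combine_masks <- function(masks) {
  if (!length(masks)) stop("no masks given", call. = FALSE)
  stopifnot(all(vapply(masks, inherits, TRUE, "pixel_mask")))
  ax <- masks[[1]]$axes
  valid <- masks[[1]]$valid
  for (m in masks[-1]) {
    stop_axes(ax, m$axes, "masks")
    valid <- valid & m$valid
  }
  pixel_mask(ax, valid)
}

#' Block-aggregate a fine raster onto a coarser grid
#'
#' Aggregates a fine-resolution monthly stack to a coarser target grid whose
#' cell size is an integer multiple of the fine cell size (e.g. 8 km-style
#' NDVI blocks to 0.5 degrees). `method = "mean"` averages the contributing
#' fine cells ignoring missing ones; an output cell is missing only when all
#' contributing cells are missing. `method = "nearest"` picks the fine cell
#' whose centre is nearest the coarse cell centre.
#'
#' @param fine A [monthly_raster()] on the fine grid.
#' @param target A [grid_axes()] for the coarse grid, covering the same extent.
#' @param method `"mean"` (block average, default) or `"nearest"`.
#' @return A [monthly_raster()] on `target`.
#' @export
aggregate_to_grid <- function(fine, target, method = c("mean", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(fine, "monthly_raster"), inherits(target, "grid_axes"))
  f <- target$cell_size / fine$axes$cell_size
  if (method == "mean" && abs(f - round(f)) > 1e-6)
    stop("fine cell size does not divide target cell size", call. = FALSE)
  f <- as.integer(round(f))
  nt <- length(fine$years)
  out <- array(NA_real_, c(nt, target$n_lat, target$n_lon))
  if (method == "mean") {
    if (fine$axes$n_lat != f * target$n_lat || fine$axes$n_lon != f * target$n_lon)
      stop("fine grid does not tile the target grid", call. = FALSE)
    # block index of each fine row/col
    bi <- rep(seq_len(target$n_lat), each = f)
    bj <- rep(seq_len(target$n_lon), each = f)
    for (t in seq_len(nt)) {
      sl <- fine$values[t, , , drop = TRUE]
      dim(sl) <- c(fine$axes$n_lat, fine$axes$n_lon)
      sums <- rowsum(sl, bi, na.rm = TRUE)
      sums <- t(rowsum(t(sums), bj, na.rm = TRUE))
      cnts <- rowsum((!is.na(sl)) * 1, bi)
      cnts <- t(rowsum(t(cnts), bj))
      m <- sums / cnts
      m[cnts == 0] <- NA_real_
      out[t, , ] <- m
    }
  } else {
    ri <- vapply(target$lat, function(la) which.min(abs(fine$axes$lat - la)), 1L)
    ci <- vapply(target$lon, function(lo) which.min(abs(fine$axes$lon - lo)), 1L)
    out <- fine$values[, ri, ci, drop = FALSE]
  }
  monthly_raster(target, fine$years, fine$months, out, fine$variable,
                 units = fine$units, validate = FALSE)
}
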