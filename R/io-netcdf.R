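#' Read and write monthly stacks as CF-style NetCDF
#'
#' NetCDF is the canonical interchange format for all gridded stacks in this
#' package: dimensions `(time, lat, lon)`, a `units` attribute on the data
#' variable, time encoded as integer `"months since YYYY-MM-15"`, and missing
#' cells stored as the declared `_FillValue` (internally they are plain `NA`).
#'
#' @param raster A [monthly_raster()] to write.
#' @param path File path of the NetCDF file.
#' @return `read_monthly_stack` returns a validated [monthly_raster()];
#'   `write_monthly_stack` returns `path` invisibly.
#' @name stack_io
NULL

.vp_fill <- -9.969210e36  # conventional CF default fill

#' @rdname stack_io
#' @export
write_monthly_stack <- function(raster, path) {
  stopifnot(inherits(raster, "monthly_raster"))
  ax <- raster$axes
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", ax$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", ax$lat)
  t0 <- sprintf("months since %04d-%02d-15", raster$years[1], raster$months[1])
  dtim <- ncdf4::ncdim_def("time", t0, seq_along(raster$years) - 1,
                           unlim = TRUE, calendar = "standard")
  var <- ncdf4::ncvar_def(raster$variable, raster$units,
                          list(dlon, dlat, dtim), missval = .vp_fill,
                          prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  # internal layout (time, lat, lon) -> file layout (lon, lat, time)
  vals <- aperm(raster$values, c(3, 2, 1))
  ncdf4::ncvar_put(nc, var, vals)
  ncdf4::ncatt_put(nc, raster$variable, "long_name", raster$variable)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  ncdf4::ncatt_put(nc, 0, "cell_registration", "center")
  ncdf4::ncatt_put(nc, 0, "cell_size_deg", ax$cell_size)
  invisible(path)
}

parse_month_origin <- function(units) {
  m <- regmatches(units,
                  regexec("months since ([0-9]{1,4})-([0-9]{1,2})", units))[[1]]
  if (length(m) != 3)
    stop("time units are not 'months since YYYY-MM-...': ", units, call. = FALSE)
  c(year = as.integer(m[2]), month = as.integer(m[3]))
}

#' @param variable Name of the variable to read; by default the single
#'   non-coordinate variable in the file.
#' @rdname stack_io
#' @export
read_monthly_stack <- function(path, variable = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  vnames <- names(nc$var)
  if (is.null(variable)) {
    if (length(vnames) != 1)
      stop("file holds several variables; name one of: ",
           paste(vnames, collapse = ", "), call. = FALSE)
    variable <- vnames[1]
  }
  if (!variable %in% vnames)
    stop("variable '", variable, "' not in file", call. = FALSE)
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  tv <- nc$dim$time
  if (is.null(tv)) stop("file has no time dimension", call. = FALSE)
  org <- parse_month_origin(tv$units)
  toff <- as.numeric(tv$vals)
  if (any(abs(toff - round(toff)) > 1e-6))
    stop("non-integer month offsets in time axis", call. = FALSE)
  midx <- org["year"] * 12L + (org["month"] - 1L) + as.integer(round(toff))
  years <- midx %/% 12L
  months <- midx %% 12L + 1L
  if (length(midx) > 1 && any(diff(midx) != 1L))
    stop("time axis is not contiguous monthly", call. = FALSE)
  csize <- ncdf4::ncatt_get(nc, 0, "cell_size_deg")
  cell <- if (csize$hasatt) csize$value else {
    if (length(lat) > 1) abs(diff(lat[1:2])) else abs(diff(lon[1:2]))
  }
  ax <- grid_axes(lat, lon, cell)
  vals <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  dim(vals) <- c(length(lon), length(lat), length(years))
  vals <- aperm(vals, c(3, 2, 1))  # -> (time, lat, lon); ncvar_get maps fill to NA
  u <- ncdf4::ncatt_get(nc, variable, "units")
  units <- if (u$hasatt) u$value else NULL
  if (variable %in% names(.vp_variables) && !is.null(units) &&
      !identical(units, unname(.vp_variables[variable])))
    stop("units '", units, "' do not match canonical units '",
         .vp_variables[variable], "' for variable '", variable, "'",
         call. = FALSE)
  monthly_raster(ax, years, months, vals, variable, units = units)
}

#' Read and write static maps as NetCDF
#'
#' Single-layer maps (elevation, CTI, soil attributes, categorical zone maps,
#' built-up flags) stored with `(lat, lon)` dimensions. Categorical kinds are
#' stored as integer codes; an attached code table travels as a pair of
#' attributes (`codes`, `labels`).
#'
#' @param map A [static_map()].
#' @param path NetCDF file path.
#' @param kind Map kind for `read_static_map`; defaults to the variable name
#'   in the file.
#' @return `read_static_map` returns a [static_map()]; `write_static_map`
#'   returns `path` invisibly.
#' @name static_io
NULL

#' @rdname static_io
#' @export
write_static_map <- function(map, path) {
  stopifnot(inherits(map, "static_map"))
  ax <- map$axes
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", ax$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", ax$lat)
  prec <- if (map$categorical) "integer" else "double"
  mv <- if (map$categorical) -2147483647L else .vp_fill
  var <- ncdf4::ncvar_def(map$kind, "1", list(dlon, dlat), missval = mv,
                          prec = prec)
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, var, t(map$values))
  ncdf4::ncatt_put(nc, 0, "cell_size_deg", ax$cell_size)
  if (!is.null(map$code_table)) {
    ncdf4::ncatt_put(nc, map$kind, "codes",
                     paste(map$code_table$code, collapse = ","))
    ncdf4::ncatt_put(nc, map$kind, "labels",
                     paste(map$code_table$label, collapse = ","))
  }
  invisible(path)
}

#' @rdname static_io
#' @export
read_static_map <- function(path, kind = NULL) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  vn <- names(nc$var)
  if (is.null(kind)) kind <- vn[1]
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  csize <- ncdf4::ncatt_get(nc, 0, "cell_size_deg")
  cell <- if (csize$hasatt) csize$value else abs(diff(lat[1:2]))
  ax <- grid_axes(lat, lon, cell)
  vals <- ncdf4::ncvar_get(nc, kind, collapse_degen = FALSE)
  dim(vals) <- c(length(lon), length(lat))
  vals <- t(vals)
  ct <- NULL
  codes <- ncdf4::ncatt_get(nc, kind, "codes")
  if (codes$hasatt) {
    labels <- ncdf4::ncatt_get(nc, kind, "labels")
    ct <- data.frame(code = as.integer(strsplit(codes$value, ",")[[1]]),
                     label = strsplit(labels$value, ",")[[1]],
                     stringsAsFactors = FALSE)
  }
  static_map(ax, vals, kind, code_table = ct)
}
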