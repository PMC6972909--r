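#' Binned averages of a map along an environmental covariate
#'
#' The binned-average analysis used to read a correlation map along a
#' gradient: pixels are grouped into uniform, left-closed right-open bins of
#' the covariate anchored at 0 (`[k*w, (k+1)*w)`), and each bin's mean and
#' SD of the value map are reported. Bins whose population falls below
#' `min_count` (default 10) are flagged excluded and carry no mean/SD.
#' Conventional plot error bars are half an SD (`sd/2`).
#'
#' Standard bin widths: 50 mm for mean annual precipitation, 0.025 for
#' fraction of precipitation days, 1 for the precipitation concentration
#' index, 1000 m for elevation, 1 for CTI.
#'
#' @param values Numeric matrix (e.g. an `r_max` map) or vector.
#' @param covariate A [static_map()], matrix or vector aligned with
#'   `values`.
#' @param bin_width Positive bin width in covariate units.
#' @param min_count Minimum bin population (default 10).
#' @param selection Optional [pixel_mask()] or logical matrix restricting
#'   the pixels used.
#' @return A data frame of class `binned_profile` with columns `bin_lo`,
#'   `bin_hi`, `mid`, `count`, `mean`, `sd`, `excluded`.
#' @export
binned_average <- function(values, covariate, bin_width, min_count = 10,
                           selection = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  cov <- if (inherits(covariate, "static_map")) covariate$values else covariate
  v <- as.vector(values); cv <- as.vector(cov)
  if (length(v) != length(cv))
    stop("values and covariate differ in length", call. = FALSE)
  keep <- !is.na(v) & !is.na(cv)
  if (!is.null(selection)) {
    sel <- if (inherits(selection, "pixel_mask")) selection$valid else selection
    keep <- keep & as.vector(sel)
  }
  v <- v[keep]; cv <- cv[keep]
  if (!length(v)) {
    out <- data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      mid = numeric(0), count = integer(0),
                      mean = numeric(0), sd = numeric(0),
                      excluded = logical(0))
    class(out) <- c("binned_profile", class(out))
    return(out)
  }
  idx <- floor(cv / bin_width)
  bins <- seq(min(idx), max(idx))
  count <- vapply(bins, function(b) sum(idx == b), 1L)
  mean_v <- rep(NA_real_, length(bins)); sd_v <- rep(NA_real_, length(bins))
  ok <- count >= min_count
  for (k in which(ok)) {
    vv <- v[idx == bins[k]]
    mean_v[k] <- mean(vv)
    sd_v[k] <- if (length(vv) > 1) stats::sd(vv) else 0
  }
  out <- data.frame(bin_lo = bins * bin_width, bin_hi = (bins + 1) * bin_width,
                    mid = (bins + 0.5) * bin_width, count = count,
                    mean = mean_v, sd = sd_v, excluded = !ok)
  class(out) <- c("binned_profile", class(out))
  out
}

#' Ecological zones as the land-cover x ecoregion intersection
#'
#' Assigns one zone id to every distinct (land-cover class, ecoregion) pair
#' present on the grid, so each zone is one vegetation class located
#' exclusively within one ecoregion. A code table mapping ids to
#' `lc<class>:er<region>` labels is attached.
#'
#' @param landcover [static_map()] of kind `"landcover_class"`.
#' @param ecoregion [static_map()] of kind `"ecoregion_id"`.
#' @return A [static_map()] of kind `"ecozone_id"` with a `code_table`.
#' @export
eco_zone_intersect <- function(landcover, ecoregion) {
  stopifnot(inherits(landcover, "static_map"), inherits(ecoregion, "static_map"))
  stop_axes(landcover$axes, ecoregion$axes, "landcover and ecoregion")
  lc <- landcover$values; er <- ecoregion$values
  pair <- ifelse(is.na(lc) | is.na(er), NA,
                 paste(lc, er, sep = ":"))
  seen <- sort(unique(stats::na.omit(as.vector(pair))))
  ids <- match(pair, seen)
  zone <- matrix(as.integer(ids), nrow(lc), ncol(lc))
  ct <- data.frame(code = seq_along(seen),
                   label = paste0("lc", sub(":", ":er", seen)),
                   stringsAsFactors = FALSE)
  static_map(landcover$axes, zone, "ecozone_id", code_table = ct)
}

#' Zonal box statistics of a correlation map
#'
#' Per ecological zone, the 5th, 25th, 50th, 75th and 95th percentiles
#' (linear interpolation between order statistics) of the value map over
#' selected pixels — the numbers behind a box-and-whisker display. Zones
#' represented by fewer than `min_pixels` pixels (default 10) are omitted.
#' Critical |r| reference lines at alpha 0.05 and 0.001 for the analysis
#' sample size are attached as an attribute.
#'
#' @param values Numeric matrix (e.g. `r_max`).
#' @param zones [static_map()] of kind `"ecozone_id"` (or an integer
#'   matrix).
#' @param selection Optional [pixel_mask()] or logical matrix.
#' @param min_pixels Minimum zone population.
#' @param n,n_controls Sample size and number of controls used for the
#'   critical-r reference lines (default 34 years, 2 controls).
#' @return A data frame of class `zone_summary` with columns `zone_id`,
#'   `label`, `count`, `p5`, `p25`, `p50`, `p75`, `p95`; attribute
#'   `critical_r` holds the alpha = 0.05 and 0.001 reference values.
#' @export
zone_boxstats <- function(values, zones, selection = NULL, min_pixels = 10,
                          n = 34, n_controls = 2) {
  zmat <- if (inherits(zones, "static_map")) zones$values else zones
  ct <- if (inherits(zones, "static_map")) zones$code_table else NULL
  v <- as.vector(values); z <- as.vector(zmat)
  keep <- !is.na(v) & !is.na(z)
  if (!is.null(selection)) {
    sel <- if (inherits(selection, "pixel_mask")) selection$valid else selection
    keep <- keep & as.vector(sel)
  }
  v <- v[keep]; z <- z[keep]
  ids <- sort(unique(z))
  rows <- lapply(ids, function(id) {
    vv <- v[z == id]
    if (length(vv) < min_pixels) return(NULL)
    q <- stats::quantile(vv, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                         names = FALSE)
    data.frame(zone_id = id,
               label = if (!is.null(ct) && id %in% ct$code)
                 ct$label[match(id, ct$code)] else as.character(id),
               count = length(vv),
               p5 = q[1], p25 = q[2], p50 = q[3], p75 = q[4], p95 = q[5],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(zone_id = integer(0), label = character(0),
                      count = integer(0), p5 = numeric(0), p25 = numeric(0),
                      p50 = numeric(0), p75 = numeric(0), p95 = numeric(0))
  attr(out, "critical_r") <- c(alpha_0.05 = critical_r(0.05, n, n_controls),
                               alpha_0.001 = critical_r(0.001, n, n_controls))
  class(out) <- c("zone_summary", class(out))
  out
}

#' Per-zone median temporal-response profiles
#'
#' For each ecological zone, the median over selected pixels of each of the
#' 24 per-combination correlation maps `r_j`, organised by (lag, cumulation
#' period) — the per-zone temporal fingerprints of vegetation response.
#'
#' @param rj An `rj_maps` object from [max_over_months()], or a bare
#'   `(24, n_lat, n_lon)` array.
#' @param zones [static_map()] of kind `"ecozone_id"` or integer matrix.
#' @param selection Optional [pixel_mask()] or logical matrix.
#' @param min_pixels Minimum zone population (default 10).
#' @return A data frame with one row per (zone, combination): `zone_id`,
#'   `label`, `count`, `j`, `lag`, `cumper`, `median_r`.
#' @export
zone_temporal_medians <- function(rj, zones, selection = NULL,
                                  min_pixels = 10) {
  arr <- if (inherits(rj, "rj_maps")) rj$r_j else rj
  combos <- if (inherits(rj, "rj_maps")) rj$combos else design_combos()
  d <- dim(arr)
  m <- arr; dim(m) <- c(d[1], d[2] * d[3])
  zmat <- if (inherits(zones, "static_map")) zones$values else zones
  ct <- if (inherits(zones, "static_map")) zones$code_table else NULL
  z <- as.vector(zmat)
  keep <- !is.na(z)
  if (!is.null(selection)) {
    sel <- if (inherits(selection, "pixel_mask")) selection$valid else selection
    keep <- keep & as.vector(sel)
  }
  ids <- sort(unique(z[keep]))
  rows <- lapply(ids, function(id) {
    cols <- which(keep & z == id)
    if (length(cols) < min_pixels) return(NULL)
    med <- apply(m[, cols, drop = FALSE], 1, stats::median, na.rm = TRUE)
    data.frame(zone_id = id,
               label = if (!is.null(ct) && id %in% ct$code)
                 ct$label[match(id, ct$code)] else as.character(id),
               count = length(cols), j = combos$j, lag = combos$lag,
               cumper = combos$cumper, median_r = med,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(zone_id = integer(0), label = character(0),
                      count = integer(0), j = integer(0), lag = integer(0),
                      cumper = integer(0), median_r = numeric(0))
  out
}
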