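#' Mean annual precipitation (MAP)
#'
#' Mean over years of the annual (12-month) precipitation totals, in mm/yr.
#' A pixel-year is missing if any of its 12 months is missing; such years are
#' skipped in the averaging.
#'
#' @param precip A [monthly_raster()] of `precip_mm`.
#' @param years Full calendar years to use (default all complete years in the
#'   stack).
#' @return A `(n_lat, n_lon)` matrix of mm/yr.
#' @export
mean_annual_precip <- function(precip, years = NULL) {
  stopifnot(inherits(precip, "monthly_raster"))
  years <- full_years(precip, years)
  ann <- annual_stat(precip, years, function(v) colSums(v, dims = 1))
  colMeans(ann, dims = 1, na.rm = TRUE)
}

full_years <- function(stack, years) {
  tab <- table(stack$years)
  complete <- as.integer(names(tab)[tab == 12])
  if (is.null(years)) return(sort(complete))
  if (!all(years %in% complete))
    stop("requested years are not complete 12-month calendar years",
         call. = FALSE)
  sort(as.integer(years))
}

annual_stat <- function(stack, years, f) {
  out <- array(NA_real_, c(length(years), stack$axes$n_lat, stack$axes$n_lon))
  for (k in seq_along(years)) {
    ti <- time_index(stack, rep(years[k], 12L), 1:12)
    out[k, , ] <- f(stack$values[ti, , , drop = FALSE])
  }
  out
}

#' Fraction of precipitation days (FPD)
#'
#' Per year, the total wet-day count divided by the number of days in the
#' year (leap-aware); averaged over years. Measures precipitation frequency
#' on a 0–1 scale.
#'
#' @param wet_days A [monthly_raster()] of `wet_days` (monthly wet-day
#'   counts).
#' @param years Full calendar years (default all complete years).
#' @return A `(n_lat, n_lon)` matrix of fractions in \[0, 1\].
#' @export
fraction_precip_days <- function(wet_days, years = NULL) {
  stopifnot(inherits(wet_days, "monthly_raster"))
  years <- full_years(wet_days, years)
  out <- array(NA_real_, c(length(years), wet_days$axes$n_lat,
                           wet_days$axes$n_lon))
  for (k in seq_along(years)) {
    ti <- time_index(wet_days, rep(years[k], 12L), 1:12)
    ylen <- sum(days_in_month(rep(years[k], 12L), 1:12))
    out[k, , ] <- colSums(wet_days$values[ti, , , drop = FALSE], dims = 1) / ylen
  }
  colMeans(out, dims = 1, na.rm = TRUE)
}

#' Precipitation concentration index (PCI)
#'
#' For twelve monthly totals \eqn{p_i},
#' \deqn{PCI = 100 \frac{\sum_{i=1}^{12} p_i^2}{(\sum_{i=1}^{12} p_i)^2}.}
#' Uniform rainfall gives 100/12 (about 8.33); all rain in one month gives
#' 100. The index is invariant to rescaling the monthly vector and undefined
#' (NA) for an all-zero year.
#'
#' @param p Numeric vector of 12 non-negative monthly precipitation totals.
#' @return The PCI value.
#' @examples
#' pci(rep(50, 12))      # 100/12
#' pci(c(600, rep(0, 11)))  # 100
#' @export
pci <- function(p) {
  if (length(p) != 12) stop("p must have 12 monthly values", call. = FALSE)
  if (anyNA(p)) return(NA_real_)
  if (any(p < 0)) stop("monthly precipitation must be non-negative", call. = FALSE)
  s <- sum(p)
  if (s <= 0) return(NA_real_)
  100 * sum(p^2) / s^2
}

#' Per-pixel PCI map
#'
#' Computes the PCI for each pixel either per year and then averaged over
#' years (`mode = "per_year"`, the default) or once from the mean monthly
#' climatology (`mode = "climatology"`). The two differ when the seasonal
#' shape varies between years; per-year averaging treats each year's
#' concentration as a sample.
#'
#' @param precip A [monthly_raster()] of `precip_mm`.
#' @param years Full calendar years (default all complete years).
#' @param mode `"per_year"` or `"climatology"`.
#' @return A `(n_lat, n_lon)` matrix of PCI values.
#' @export
pci_map <- function(precip, years = NULL, mode = c("per_year", "climatology")) {
  mode <- match.arg(mode)
  stopifnot(inherits(precip, "monthly_raster"))
  years <- full_years(precip, years)
  pci_of <- function(v) {
    # v: (12, n_lat, n_lon)
    s <- colSums(v, dims = 1)
    q <- colSums(v^2, dims = 1)
    out <- 100 * q / s^2
    out[!is.finite(out)] <- NA_real_
    out
  }
  if (mode == "climatology") {
    clim <- array(NA_real_, c(12, precip$axes$n_lat, precip$axes$n_lon))
    for (m in 1:12) {
      sel <- precip$months == m & precip$years %in% years
      clim[m, , ] <- colMeans(precip$values[sel, , , drop = FALSE], dims = 1)
    }
    return(pci_of(clim))
  }
  per <- annual_stat(precip, years, pci_of)
  colMeans(per, dims = 1, na.rm = TRUE)
}

#' Solar radiation from sunshine hours (Angstrom formula)
#'
#' \deqn{R_s = (a_s + b_s\, n/N)\, R_a,} estimating surface solar radiation
#' from the relative sunshine duration. Defaults `a_s = 0.25`, `b_s = 0.50`
#' are the standard FAO-56 coefficients used when no local calibration is
#' available.
#'
#' @param n Actual sunshine hours (scalar, vector, or array).
#' @param N Maximum possible sunshine hours (same shape as `n`).
#' @param R_a Extraterrestrial radiation, MJ m-2 d-1.
#' @param a_s,b_s Angstrom coefficients (> 0).
#' @return Solar radiation `R_s`, MJ m-2 d-1, same shape as the inputs.
#' @examples
#' angstrom_radiation(n = 6, N = 12, R_a = 30)  # 15
#' @export
angstrom_radiation <- function(n, N, R_a, a_s = 0.25, b_s = 0.50) {
  if (a_s <= 0 || b_s <= 0) stop("Angstrom coefficients must be positive",
                                 call. = FALSE)
  bad <- !is.na(n) & !is.na(N) & (n < 0 | n > N)
  if (any(bad)) stop("sunshine hours must satisfy 0 <= n <= N", call. = FALSE)
  (a_s + b_s * n / N) * R_a
}

#' Precipitation-index threshold selection
#'
#' Selects pixels whose mean annual precipitation, fraction of precipitation
#' days, and precipitation concentration index fall inside given closed
#' ranges — the precipitation conditions under which NDVI–precipitation
#' correlations peak. Defaults: MAP 150–500 mm, FPD 0.075–0.275, PCI 19–23.
#'
#' @param indices A list with matrices `map_mm`, `fpd`, `pci` on one grid
#'   (as returned by [precip_index_maps()]).
#' @param ranges A list of `c(lower, upper)` for `map_mm`, `fpd`, `pci`.
#' @param mode `"overlap"` (single conjunction mask, default) or `"each"`
#'   (one mask per index).
#' @return A [pixel_mask()] for `"overlap"`, or a named list of three
#'   [pixel_mask()]s for `"each"`.
#' @export
threshold_select <- function(indices,
                             ranges = list(map_mm = c(150, 500),
                                           fpd = c(0.075, 0.275),
                                           pci = c(19, 23)),
                             mode = c("overlap", "each")) {
  mode <- match.arg(mode)
  ax <- indices$axes
  stopifnot(inherits(ax, "grid_axes"))
  one <- function(v, rg) {
    if (rg[1] >= rg[2]) stop("threshold lower bound must be below upper",
                             call. = FALSE)
    ok <- !is.na(v) & v >= rg[1] & v <= rg[2]
    pixel_mask(ax, ok)
  }
  masks <- list(map_mm = one(indices$map_mm, ranges$map_mm),
                fpd = one(indices$fpd, ranges$fpd),
                pci = one(indices$pci, ranges$pci))
  if (mode == "each") masks else combine_masks(masks)
}

#' Compute all three precipitation-characteristic index maps
#'
#' @param precip [monthly_raster()] of `precip_mm`.
#' @param wet_days [monthly_raster()] of `wet_days`.
#' @param years Full calendar years (default all complete years common to
#'   both stacks).
#' @param pci_mode Passed to [pci_map()].
#' @return A list with `axes`, `map_mm`, `fpd`, `pci`.
#' @export
precip_index_maps <- function(precip, wet_days, years = NULL,
                              pci_mode = "per_year") {
  stop_axes(precip$axes, wet_days$axes, "precip and wet_days")
  if (is.null(years))
    years <- intersect(full_years(precip, NULL), full_years(wet_days, NULL))
  list(axes = precip$axes,
       map_mm = mean_annual_precip(precip, years),
       fpd = fraction_precip_days(wet_days, years),
       pci = pci_map(precip, years, mode = pci_mode))
}
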