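#' Default pipeline configuration
#'
#' The shipped defaults reproduce the standard analysis setup on a synthetic
#' grid: significance level 0.05; matched control windows; growing season
#' April–October; climatology base period 1982–2015; precipitation-index
#' thresholds 150–500 mm (MAP), 0.075–0.275 (FPD), 19–23 (PCI); bin widths
#' 50 mm / 0.025 / 1 for the three indices and 1000 m / 1 / 0.1 g cm-3 /
#' 50 mm for elevation, CTI, soil bulk density and available water capacity;
#' minimum bin and zone population 10.
#'
#' @param seed Master seed recorded in the config.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 42L) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(n_lat = 20L, n_lon = 20L, years = c(1981L, 2015L)),
    inputs = NULL,
    base_period = c(1982L, 2015L),
    alpha = 0.05,
    controls_window = "matched",
    thresholds = list(map_mm = c(150, 500), fpd = c(0.075, 0.275),
                      pci = c(19, 23)),
    bin_widths = list(map_mm = 50, fpd = 0.025, pci = 1,
                      elevation_m = 1000, cti = 1, sbd_g_cm3 = 0.1,
                      pawc_mm = 50),
    min_count = 10L
  ), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML key/value sections merged over [default_pipeline_config()], so a
#' config file only needs to state what it changes.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_pipeline_config()), user)
  if (!is.null(user$synthetic) && !is.null(cfg$inputs)) cfg$inputs <- NULL
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Runs every range and consistency check and returns the failures as
#' human-readable messages (an empty character vector means the config is
#' valid).
#'
#' @param config A `pipeline_config` (or plain list).
#' @return Character vector of failure messages.
#' @export
validate_config <- function(config) {
  fails <- character(0)
  add <- function(msg) fails <<- c(fails, msg)
  if (is.null(config$synthetic) == is.null(config$inputs))
    add("exactly one of 'synthetic' and 'inputs' must be present")
  a <- config$alpha
  if (is.null(a) || !is.numeric(a) || a <= 0 || a >= 1)
    add("alpha out of (0,1)")
  for (nm in names(config$thresholds)) {
    rg <- config$thresholds[[nm]]
    if (length(rg) != 2 || rg[1] >= rg[2])
      add(paste0("threshold '", nm, "': lower bound must be below upper"))
  }
  for (nm in names(config$bin_widths))
    if (config$bin_widths[[nm]] <= 0)
      add(paste0("bin width '", nm, "' must be positive"))
  if (!is.null(config$min_count) && config$min_count < 1)
    add("min_count must be >= 1")
  bp <- config$base_period
  if (length(bp) != 2 || bp[2] - bp[1] + 1 < 2)
    add("base period must span at least 2 years")
  if (!is.null(config$controls_window) &&
      !config$controls_window %in% c("matched", "lag0"))
    add("controls_window must be 'matched' or 'lag0'")
  if (!is.null(config$inputs)) {
    needed <- c("ndvi", "precip", "temp", "radiation", "wet_days")
    for (nm in needed) {
      p <- config$inputs[[nm]]
      if (is.null(p)) add(paste0("inputs: missing path for '", nm, "'"))
      else if (!file.exists(p)) add(paste0("inputs: file not found: ", p))
    }
  }
  fails
}

load_pipeline_inputs <- function(config, seed) {
  if (!is.null(config$synthetic)) {
    sb <- config$synthetic
    yr <- sb$years
    years <- if (length(yr) == 2) yr[1]:yr[2] else yr
    extra <- sb[setdiff(names(sb), c("n_lat", "n_lon", "years", "seed"))]
    sc <- do.call(synth_config,
                  c(list(n_lat = sb$n_lat, n_lon = sb$n_lon, years = years,
                         seed = seed), extra))
    climate <- generate_climate(sc)
    landscape <- generate_landscape(sc)
    veg <- generate_ndvi(climate, sc, landscape = landscape)
    list(climate = climate, landscape = landscape, ndvi = veg$ndvi,
         truth = veg$truth)
  } else {
    inp <- config$inputs
    climate <- list(precip = read_monthly_stack(inp$precip, "precip_mm"),
                    temp = read_monthly_stack(inp$temp, "temp_C"),
                    radiation = read_monthly_stack(inp$radiation,
                                                   "radiation_MJ_m2_d"),
                    wet_days = read_monthly_stack(inp$wet_days, "wet_days"))
    landscape <- list()
    for (nm in c("landcover", "ecoregion", "elevation", "cti", "sbd",
                 "pawc", "builtup"))
      if (!is.null(inp[[nm]])) landscape[[nm]] <- read_static_map(inp[[nm]])
    if (!is.null(landscape$landcover) && !is.null(landscape$ecoregion))
      landscape$ecozone <- eco_zone_intersect(landscape$landcover,
                                              landscape$ecoregion)
    list(climate = climate, landscape = landscape,
         ndvi = read_monthly_stack(inp$ndvi, "ndvi"), truth = NULL)
  }
}

write_results_nc <- function(path, cube, rj, summ) {
  ax <- cube$axes
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", ax$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", ax$lat)
  dmon <- ncdf4::ncdim_def("month", "month_of_year", cube$months)
  dcmb <- ncdf4::ncdim_def("combo", "design_index", cube$combos$j)
  dd <- function(nm, dims) ncdf4::ncvar_def(nm, "1", dims, missval = .vp_fill,
                                            prec = "double")
  vars <- list(
    r_cube = dd("r_cube", list(dlon, dlat, dcmb, dmon)),
    p_cube = dd("p_cube", list(dlon, dlat, dcmb, dmon)),
    r_j = dd("r_j", list(dlon, dlat, dcmb)),
    r_max = dd("r_max", list(dlon, dlat)),
    best_lag = dd("best_lag", list(dlon, dlat)),
    best_cumper = dd("best_cumper", list(dlon, dlat)),
    any_significant = dd("any_significant", list(dlon, dlat)))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, vars$r_cube, aperm(cube$r, c(4, 3, 2, 1)))
  ncdf4::ncvar_put(nc, vars$p_cube, aperm(cube$p, c(4, 3, 2, 1)))
  ncdf4::ncvar_put(nc, vars$r_j, aperm(rj$r_j, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, vars$r_max, t(summ$r_max))
  ncdf4::ncvar_put(nc, vars$best_lag, t(summ$best_lag))
  ncdf4::ncvar_put(nc, vars$best_cumper, t(summ$best_cumper))
  ncdf4::ncvar_put(nc, vars$any_significant, t(summ$any_significant * 1))
  invisible(path)
}

write_seasonal_nc <- function(path, sset) {
  ax <- sset$axes
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", ax$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", ax$lat)
  dsea <- ncdf4::ncdim_def("season", "index", seq_along(sset$seasons))
  dmod <- ncdf4::ncdim_def("mode", "index", seq_along(sset$modes))
  vr <- ncdf4::ncvar_def("r_seasonal", "1", list(dlon, dlat, dmod, dsea),
                         missval = .vp_fill, prec = "double")
  vp <- ncdf4::ncvar_def("p_seasonal", "1", list(dlon, dlat, dmod, dsea),
                         missval = .vp_fill, prec = "double")
  nc <- ncdf4::nc_create(path, list(vr, vp))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  ncdf4::ncvar_put(nc, vr, aperm(sset$r, c(4, 3, 2, 1)))
  ncdf4::ncvar_put(nc, vp, aperm(sset$p, c(4, 3, 2, 1)))
  ncdf4::ncatt_put(nc, 0, "seasons", paste(sset$seasons, collapse = ","))
  ncdf4::ncatt_put(nc, 0, "modes", paste(sset$modes, collapse = ","))
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes generation (or input loading), preprocessing, index computation,
#' the monthly lag/cumulation correlation analysis, the seasonal modes, and
#' the attribution stage, writing every product plus a manifest of output
#' files with content hashes to `out_dir`. Deterministic: the same config
#' and seed give byte-identical outputs.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()],
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory results (`cube`, `rj`,
#'   `summary`, `seasonal`, `indices`, `profiles`, `zone_stats`,
#'   `zone_medians`, `trend`, `significance`, `manifest`).
#' @export
run_full <- function(config = default_pipeline_config(), out_dir,
                     seed = NULL, quiet = FALSE) {
  fails <- validate_config(config)
  if (length(fails))
    stop("invalid config:\n  ", paste(fails, collapse = "\n  "), call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()
  outputs <- character(0)
  keep <- function(p) { outputs <<- c(outputs, p); p }

  say("stage 1/6: inputs (seed %d)", seed)
  inp <- load_pipeline_inputs(config, seed)
  climate <- inp$climate; landscape <- inp$landscape; ndvi <- inp$ndvi
  if (!is.null(inp$truth))
    keep(write_truth_table(inp$truth, file.path(out_dir, "truth.tsv")))

  say("stage 2/6: preprocessing")
  qc <- qc_mask(ndvi, builtup = landscape$builtup)
  bp <- config$base_period
  bp[1] <- max(bp[1], min(ndvi$years)); bp[2] <- min(bp[2], max(ndvi$years))
  ndvi_ano <- monthly_anomalies(ndvi, bp)
  p_ano <- monthly_anomalies(climate$precip, bp)
  t_ano <- monthly_anomalies(climate$temp, bp)
  r_ano <- monthly_anomalies(climate$radiation, bp)
  gs <- seasonal_aggregate(ndvi, "growing", years = bp[1]:bp[2])
  gs_series <- area_weighted_mean(gs, qc)
  trend <- ols_trend(gs_series, gs$years)

  say("stage 3/6: precipitation indices")
  indices <- precip_index_maps(climate$precip, climate$wet_days,
                               years = bp[1]:bp[2])
  overlap <- threshold_select(indices, config$thresholds, mode = "overlap")

  say("stage 4/6: monthly lag x cumulation correlations")
  cube <- monthly_lagcum_correlations(ndvi_ano, p_ano, t_ano, r_ano,
                                      mask = qc, alpha = config$alpha,
                                      controls_window = config$controls_window)
  rj <- max_over_months(cube)
  summ <- max_over_combos(rj, cube)
  sig <- significance_summary(cube, qc)
  bl <- best_lag_map(rj, summ)
  bc <- best_cum_map(rj, summ)
  keep(write_results_nc(file.path(out_dir, "temporal_response.nc"),
                        cube, rj, summ))
  keep(write_tsv(bl$shares, file.path(out_dir, "lag_shares.tsv")))
  keep(write_tsv(bc$shares, file.path(out_dir, "cumper_shares.tsv")))

  say("stage 5/6: seasonal modes")
  sset <- seasonal_parcorr(ndvi, climate$precip, climate$temp,
                           climate$radiation, mask = qc,
                           alpha = config$alpha, years = cube$years)
  keep(write_seasonal_nc(file.path(out_dir, "seasonal_response.nc"), sset))

  say("stage 6/6: attribution")
  sel <- combine_masks(list(overlap, qc))
  profiles <- list()
  covs <- list(map_mm = indices$map_mm, fpd = indices$fpd, pci = indices$pci)
  for (nm in c("elevation", "cti", "sbd", "pawc")) {
    kinds <- c(elevation = "elevation_m", cti = "cti", sbd = "sbd_g_cm3",
               pawc = "pawc_mm")
    if (!is.null(landscape[[nm]])) covs[[kinds[[nm]]]] <- landscape[[nm]]$values
  }
  for (nm in names(covs)) {
    use_sel <- if (nm %in% c("map_mm", "fpd", "pci")) qc$valid else sel$valid
    prof <- binned_average(summ$r_max, covs[[nm]],
                           bin_width = config$bin_widths[[nm]],
                           min_count = config$min_count, selection = use_sel)
    profiles[[nm]] <- prof
    keep(write_tsv(prof, file.path(out_dir, paste0("profile_", nm, ".tsv"))))
  }
  zone_stats <- zone_medians <- NULL
  if (!is.null(landscape$ecozone)) {
    zone_stats <- zone_boxstats(summ$r_max, landscape$ecozone, sel$valid,
                                min_pixels = config$min_count,
                                n = cube$n, n_controls = 2)
    zone_medians <- zone_temporal_medians(rj, landscape$ecozone, sel$valid,
                                          min_pixels = config$min_count)
    keep(write_tsv(zone_stats, file.path(out_dir, "zone_boxstats.tsv")))
    keep(write_tsv(zone_medians, file.path(out_dir, "zone_medians.tsv")))
  }

  summary_json <- list(
    seed = seed,
    grid = c(cube$axes$n_lat, cube$axes$n_lon),
    analysis_years = range(cube$years),
    alpha = config$alpha,
    percent_significant = sig$percent_significant,
    ndvi_trend_per_year = trend$slope,
    ndvi_trend_r_squared = trend$r_squared,
    lag_shares = stats::setNames(bl$shares$percent, bl$shares$lag),
    cumper_shares = stats::setNames(bc$shares$percent, bc$shares$cumper),
    n_overlap_pixels = sum(sel$valid))
  jp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  keep(jp)

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  invisible(list(cube = cube, rj = rj, summary = summ, seasonal = sset,
                 indices = indices, overlap = overlap, qc = qc,
                 profiles = profiles, zone_stats = zone_stats,
                 zone_medians = zone_medians, trend = trend,
                 significance = sig, shares_lag = bl$shares,
                 shares_cum = bc$shares, truth = inp$truth,
                 manifest = manifest))
}
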