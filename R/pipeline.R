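pipelineDefaults <- function() {
  list(
    mode = "synthetic",          # "synthetic" or "files"
    seed = 1L,
    n_cities = 50L,
    zipf_exponent = 2,
    slope_city = 0.003,
    slope_land = 0.001,
    resid_sd = 0.01,
    years = 1982:2013,
    profile = "u_shape",
    dn_threshold = 12L,
    connectivity = 8L,
    inclusive_threshold = TRUE,
    bin_width = 0.1,
    spectrum_base_km2 = 2,
    trend_interval = c(0.2, 0.5),
    green_ratio_min = 2,
    brown_band = 0.25,
    city_cover_cutoff = 0.5,
    light_path = NULL,           # files mode
    ndvi_dir = NULL, ndvi_stem = "ndvi",
    e_path = NULL, h_path = NULL, p_path = NULL,
    abundance_path = NULL, threatened_path = NULL,
    out_dir = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list or YAML file against the documented keys
#' and ranges. Unknown keys produce warnings; violated ranges, missing
#' required keys and missing input files produce errors.
#'
#' @param config a named list or the path of a YAML file.
#' @return list with character vectors `errors` and `warnings`; valid when
#'   `length(errors) == 0`.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) return(list(errors = "config must be a mapping",
                                    warnings = character()))
  defs <- pipelineDefaults()
  errors <- character(); warnings <- character()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    warnings <- c(warnings, paste("unknown key(s):",
                                  paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defs, config[intersect(names(config),
                                                  names(defs))])
  if (!cfg$mode %in% c("synthetic", "files"))
    errors <- c(errors, "mode must be 'synthetic' or 'files'")
  if (cfg$dn_threshold < 0 || cfg$dn_threshold > 63)
    errors <- c(errors, "dn_threshold must lie in [0, 63]")
  if (!cfg$connectivity %in% c(4, 8))
    errors <- c(errors, "connectivity must be 4 or 8")
  if (cfg$bin_width <= 0 || cfg$bin_width > 1)
    errors <- c(errors, "bin_width must lie in (0, 1]")
  if (cfg$spectrum_base_km2 <= 0)
    errors <- c(errors, "spectrum_base_km2 must be positive")
  if (length(cfg$trend_interval) != 2 ||
      cfg$trend_interval[1] >= cfg$trend_interval[2])
    errors <- c(errors, "trend_interval must be an increasing pair")
  if (cfg$mode == "files") {
    need <- c("light_path", "ndvi_dir", "e_path", "h_path", "p_path")
    for (key in need)
      if (is.null(cfg[[key]]))
        errors <- c(errors, paste(key, "is required in files mode"))
      else if (!file.exists(cfg[[key]]))
        errors <- c(errors, paste(key, "does not exist:", cfg[[key]]))
    if (is.null(cfg$abundance_path) || is.null(cfg$threatened_path))
      errors <- c(errors,
                  "species layers are required for the summary table")
  }
  list(errors = errors, warnings = warnings)
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the full chain from a single configuration: city
#' extraction and sizing, the exponential size spectrum, (E, H) state-space
#' embeddings (number density and NDVI-, abundance- and threatened-weighted),
#' per-stratum NDVI-bin statistics, NDVI/city percentage curves, the
#' city-versus-land trend comparison with green/brown classification, the
#' size-conditioned statistics and the urbanization summary table. All
#' tables are written as CSV under `out_dir` (when set) together with a
#' run manifest recording the configuration and per-file MD5 sums, making
#' reruns verifiable.
#'
#' @param config named list or YAML path; see [validateConfig()] for keys.
#'   In `"synthetic"` mode (default) the inputs are generated by
#'   [simulateWorld()] from `seed`.
#' @return list with components `cities`, `spectrum`, `histograms`,
#'   `binStats`, `ndviPct`, `cityPct`, `trend`, `sizeStats`, `table1`,
#'   `manifest` (and `world` in synthetic mode).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  chk <- validateConfig(config)
  if (length(chk$errors))
    stop("invalid config: ", paste(chk$errors, collapse = "; "))
  for (w in chk$warnings) warning(w)
  cfg <- utils::modifyList(pipelineDefaults(),
                           config[intersect(names(config),
                                            names(pipelineDefaults()))])

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  world <- NULL
  if (cfg$mode == "synthetic") {
    world <- stage("simulate", simulateWorld(
      nCities = cfg$n_cities, zipfExponent = cfg$zipf_exponent,
      slopeCity = cfg$slope_city, slopeLand = cfg$slope_land,
      residSd = cfg$resid_sd, years = cfg$years,
      profile = cfg$profile, seed = cfg$seed))
    light <- world$light; ndvi <- world$ndvi
    ndviClim <- GridRaster(world$ndviClim, world$grid$latEdges,
                           world$grid$lonEdges, name = "ndvi_clim")
    E <- world$E; H <- world$H
    abundance <- world$abundance; threatened <- world$threatened
  } else {
    light <- stage("read lights", readRaster(cfg$light_path, "lights"))
    ndvi <- stage("read ndvi",
                  readTimeRaster(cfg$ndvi_dir, cfg$ndvi_stem))
    ndviClim <- climatology(ndvi)
    E <- stage("read E", readRaster(cfg$e_path, "E"))
    H <- stage("read H", readRaster(cfg$h_path, "H"))
    abundance <- stage("read abundance",
                       readRaster(cfg$abundance_path, "abundance"))
    threatened <- stage("read threatened",
                        readRaster(cfg$threatened_path, "threatened"))
  }

  cities <- stage("extract cities", citySizes(extractCities(
    light, dnThreshold = cfg$dn_threshold,
    connectivity = cfg$connectivity,
    inclusive = cfg$inclusive_threshold)))
  spectrum <- stage("size spectrum",
                    sizeSpectrum(cities, baseKm2 = cfg$spectrum_base_km2))
  cover <- stage("city mask", cityMask(cities))
  masks <- stratumMasks(cover, cutoff = cfg$city_cover_cutoff)
  areas <- pixelAreaKm2(ndviClim)
  cv <- stage("ndvi variability", coefficientOfVariability(ndvi))

  histograms <- stage("state-space embedding", {
    mx <- max(gridValues(E) + gridValues(H), na.rm = TRUE)
    edges <- seq(0, ceiling(mx * 10) / 10, by = 0.1)
    list(
      density = embedStateSpace(E, H, eEdges = edges, hEdges = edges),
      ndvi = embedStateSpace(E, H, ndviClim, eEdges = edges,
                             hEdges = edges),
      abundance = embedStateSpace(E, H, abundance, eEdges = edges,
                                  hEdges = edges),
      threatened = embedStateSpace(E, H, threatened, eEdges = edges,
                                   hEdges = edges)
    )
  })

  bs <- stage("bin statistics", do.call(rbind, lapply(
    c("land", "city", "non_city"), function(s)
      binStats(ndviClim, abundance, threatened, cv = cv,
               mask = masks[[s]], areas = areas,
               binWidth = cfg$bin_width, stratum = s))))
  ndviPct <- stage("ndvi percentage",
                   ndviPercentage(ndviClim, masks$land, areas,
                                  cfg$bin_width))
  cityPct <- stage("city percentage",
                   cityPercentage(ndviClim, masks$city, areas,
                                  cfg$bin_width))
  trend <- stage("trend comparison", compareTrends(
    ndvi, masks$city, masks$land, interval = cfg$trend_interval,
    ndviClim = ndviClim, areas = areas,
    greenRatioMin = cfg$green_ratio_min, brownBand = cfg$brown_band))
  sizeStats <- stage("size-conditioned statistics",
                     sizeConditionedStats(cities, spectrum, ndviClim,
                                          abundance, threatened, areas))
  # two-region split (west/east halves) exercises the summary structure
  nlon2 <- ncol(gridValues(ndviClim)) %/% 2L
  regA <- matrix(FALSE, nrow(gridValues(ndviClim)),
                 ncol(gridValues(ndviClim)))
  regA[, seq_len(nlon2)] <- TRUE
  regB <- !regA
  tbl1 <- stage("summary table", table1Summary(
    regions = list(west = regA, east = regB,
                   global = regA | regB),
    abundance = list(vertebrates = abundance),
    threatened = list(vertebrates = threatened),
    cityStratum = masks$city, areas = areas))

  manifest <- list(config = cfg[order(names(cfg))],
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"))
  out <- list(cities = cities, spectrum = spectrum,
              histograms = histograms, binStats = bs, ndviPct = ndviPct,
              cityPct = cityPct, trend = trend, sizeStats = sizeStats,
              table1 = tbl1, manifest = manifest, world = world)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(df, name) {
      p <- file.path(cfg$out_dir, paste0(name, ".csv"))
      utils::write.csv(df, p, row.names = FALSE)
      p
    }
    paths <- c(
      wcsv(as.data.frame(cities), "cities"),
      wcsv(as.data.frame(spectrum), "size_spectrum"),
      wcsv(as.data.frame(histograms$density), "state_space_density"),
      wcsv(bs, "bin_stats"),
      wcsv(ndviPct$bins, "ndvi_percentage"),
      wcsv(cityPct$bins, "city_percentage"),
      wcsv(as.data.frame(trend), "trend_comparison"),
      wcsv(sizeStats$perBin, "size_conditioned_stats"),
      wcsv(tbl1, "table1_summary")
    )
    manifest$outputs <- as.list(stats::setNames(
      as.character(tools::md5sum(paths)), basename(paths)))
    out$manifest <- manifest
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
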