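#' A toy world grid for the synthetic generators
#'
#' 200 x 200 cells spanning 100 degrees of latitude and longitude (0.5
#' degree cells) by default, so pixel areas vary noticeably with latitude.
#'
#' @param nlat,nlon cell counts.
#' @param latRange,lonRange extents in degrees.
#' @return list with `latEdges`, `lonEdges`.
#' @export
syntheticGrid <- function(nlat = 200L, nlon = 200L,
                          latRange = c(-50, 50), lonRange = c(0, 100)) {
  list(latEdges = seq(latRange[1], latRange[2], length.out = nlat + 1L),
       lonEdges = seq(lonRange[1], lonRange[2], length.out = nlon + 1L))
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic nighttime-light raster
#'
#' Cities are compact connected blobs grown by randomized dilation from
#' random seed pixels, with pixel counts drawn from a discrete power law
#' `P(k) proportional to k^-zipfExponent` on `1..maxPixels` (small cities
#' common, megacities rare). City pixels carry DN in \[12, 63\], background
#' DN in \[0, 11\]. Blobs may merge; the truth record counts the resulting
#' components.
#'
#' @param grid from [syntheticGrid()].
#' @param nCities number of planted blobs (`>= 1`).
#' @param zipfExponent power-law exponent of the pixel-count distribution.
#' @param maxPixels largest blob pixel count.
#' @param seed RNG seed.
#' @return list with `light` (a [GridRaster-class]) and `truth` (planted
#'   centers, pixel counts, exponent, achieved component count, merges).
#' @export
genLights <- function(grid = syntheticGrid(), nCities = 50L,
                      zipfExponent = 2, maxPixels = 256L, seed = 1L) {
  nlat <- length(grid$latEdges) - 1L
  nlon <- length(grid$lonEdges) - 1L
  if (nCities < 1L) stop("nCities must be >= 1")
  if (nCities * 4L > nlat * nlon)
    stop("grid too small for the requested number of cities")
  withSeed(seed, {
    k <- sample.int(maxPixels, nCities, replace = TRUE,
                    prob = (seq_len(maxPixels))^(-zipfExponent))
    dn <- matrix(sample(0:11, nlat * nlon, replace = TRUE), nlat, nlon)
    cityPix <- matrix(FALSE, nlat, nlon)
    centers <- cbind(row = sample.int(nlat, nCities, replace = TRUE),
                     col = sample.int(nlon, nCities, replace = TRUE))
    achieved <- integer(nCities)
    for (j in seq_len(nCities)) {
      blob <- matrix(centers[j, ], ncol = 2)
      inBlob <- paste(blob[, 1], blob[, 2])
      while (nrow(blob) < k[j]) {
        # frontier: 4-neighbors of blob cells, inside the grid, not in blob
        fr <- rbind(cbind(blob[, 1] + 1L, blob[, 2]),
                    cbind(blob[, 1] - 1L, blob[, 2]),
                    cbind(blob[, 1], blob[, 2] + 1L),
                    cbind(blob[, 1], blob[, 2] - 1L))
        fr <- fr[fr[, 1] >= 1L & fr[, 1] <= nlat &
                 fr[, 2] >= 1L & fr[, 2] <= nlon, , drop = FALSE]
        key <- paste(fr[, 1], fr[, 2])
        fr <- fr[!key %in% inBlob, , drop = FALSE]
        if (!nrow(fr)) break
        pick <- fr[sample.int(nrow(fr), 1L), ]
        blob <- rbind(blob, pick)
        inBlob <- c(inBlob, paste(pick[1], pick[2]))
      }
      achieved[j] <- nrow(blob)
      cityPix[blob] <- TRUE
    }
    dn[cityPix] <- sample(12:63, sum(cityPix), replace = TRUE)
    nComp <- max(labelComponents(cityPix, 8L))
    light <- GridRaster(dn, grid$latEdges, grid$lonEdges, nodata = -9999,
                        name = "lights")
    list(light = light,
         truth = list(seed = seed, n_cities = nCities,
                      zipf_exponent = zipfExponent,
                      centers = centers, target_pixels = k,
                      achieved_pixels = achieved,
                      n_components = nComp,
                      n_merged = nCities - nComp))
  })
}

#' Generate an annual NDVI series with planted stratum trends
#'
#' `NDVI(t) = clim + slope_stratum * (t - mean(t)) + eps`, with
#' `eps ~ N(0, residSd)` i.i.d. per pixel and year. City pixels get
#' `slopeCity`, all others `slopeLand`. Values are clipped to \[-0.1, 1\]
#' and clip events are counted in the truth record.
#'
#' @param grid from [syntheticGrid()].
#' @param climField numeric matrix (or scalar) of climatological NDVI.
#' @param cityPixels logical matrix of city membership at this resolution.
#' @param slopeCity,slopeLand planted trends, NDVI/yr.
#' @param residSd residual noise SD (NDVI units).
#' @param years integer years (default 1982:2013, 32 years).
#' @param seed RNG seed.
#' @return list with `series` (a [TimeRaster-class]) and `truth`.
#' @export
genNdviSeries <- function(grid = syntheticGrid(), climField = 0.3,
                          cityPixels, slopeCity = 0.003,
                          slopeLand = 0.001, residSd = 0.01,
                          years = 1982:2013, seed = 1L) {
  nlat <- length(grid$latEdges) - 1L
  nlon <- length(grid$lonEdges) - 1L
  if (length(climField) == 1L) climField <- matrix(climField, nlat, nlon)
  slope <- matrix(slopeLand, nlat, nlon)
  slope[cityPixels] <- slopeCity
  tc <- years - mean(years)
  withSeed(seed, {
    arr <- array(NA_real_, c(nlat, nlon, length(years)))
    nClip <- 0L
    for (kk in seq_along(years)) {
      layer <- climField + slope * tc[kk] +
        stats::rnorm(nlat * nlon, sd = residSd)
      nClip <- nClip + sum(layer < -0.1 | layer > 1)
      arr[, , kk] <- pmin(pmax(layer, -0.1), 1)
    }
    series <- TimeRaster(arr, grid$latEdges, grid$lonEdges, years,
                         name = "ndvi")
    list(series = series,
         truth = list(seed = seed, slope_city = slopeCity,
                      slope_land = slopeLand, resid_sd = residSd,
                      years = years, n_clipped = nClip))
  })
}

#' Generate Schreiber-consistent flux fields
#'
#' From precipitation `P` and dryness `D` fields:
#' `E = P * (1 - exp(-D))` and `H = P * D - E`, so every pixel satisfies
#' both the Schreiber equation of state and the energy balance
#' `N = E + H = P * D` exactly, by construction.
#'
#' @param grid from [syntheticGrid()].
#' @param P numeric matrix or scalar precipitation (m/yr, `> 0`).
#' @param D numeric matrix or scalar dryness ratio (`> 0`).
#' @return list of [GridRaster-class] layers `E`, `H`, `P`, `D`.
#' @export
genFluxes <- function(grid = syntheticGrid(), P = 1, D = 1) {
  nlat <- length(grid$latEdges) - 1L
  nlon <- length(grid$lonEdges) - 1L
  if (length(P) == 1L) P <- matrix(P, nlat, nlon)
  if (length(D) == 1L) D <- matrix(D, nlat, nlon)
  if (any(P <= 0, na.rm = TRUE) || any(D <= 0, na.rm = TRUE))
    stop("P and D must be positive")
  E <- P * (1 - exp(-D))
  H <- P * D - E
  g <- function(v, nm) GridRaster(v, grid$latEdges, grid$lonEdges,
                                  nodata = -9999, name = nm)
  list(E = g(E, "E"), H = g(H, "H"), P = g(P, "P"), D = g(D, "D"))
}

#' Generate species abundance and threatened-count rasters
#'
#' Abundance is `Poisson(lambda(NDVI))` with a monotone non-decreasing
#' link `lambda = lambda0 + lambda1 * max(NDVI, 0)`; threatened counts are
#' a binomial thinning `Binomial(abundance, pi(bin))` where the
#' per-NDVI-bin probability follows the planted profile:
#'
#' * `u_shape` - quadratic in bin index with minimum `piMin` at
#'   `argminBin` rising to `piMax` at the farthest bin;
#' * `step_jump` - `piLow` below `thresholdBin`, `piHigh` from it upward;
#' * `flat` - constant `piFlat`.
#'
#' Thinning guarantees `threatened <= abundance`, so the indicator lies in
#' \[0, 1\].
#'
#' @param grid from [syntheticGrid()].
#' @param ndviClim numeric matrix of climatological NDVI.
#' @param lambda0,lambda1 abundance link parameters.
#' @param profile `"u_shape"`, `"step_jump"` or `"flat"`.
#' @param argminBin lower edge of the U-minimum bin (default 0.3).
#' @param thresholdBin lower edge of the step bin (default 0.4).
#' @param piMin,piMax,piLow,piHigh,piFlat profile probabilities.
#' @param binWidth NDVI bin width (default 0.1).
#' @param seed RNG seed.
#' @return list with `abundance`, `threatened` ([GridRaster-class]) and
#'   `truth` (planted profile and per-bin probabilities).
#' @export
genSpecies <- function(grid = syntheticGrid(), ndviClim,
                       lambda0 = 20, lambda1 = 200,
                       profile = c("u_shape", "step_jump", "flat"),
                       argminBin = 0.3, thresholdBin = 0.4,
                       piMin = 0.02, piMax = 0.3, piLow = 0.05,
                       piHigh = 0.3, piFlat = 0.1, binWidth = 0.1,
                       seed = 1L) {
  profile <- match.arg(profile)
  nlat <- length(grid$latEdges) - 1L
  nlon <- length(grid$lonEdges) - 1L
  if (length(ndviClim) == 1L) ndviClim <- matrix(ndviClim, nlat, nlon)
  edges <- ndviBinEdges(binWidth)
  nb <- length(edges) - 1L
  binIdx <- ndviBinIndex(as.vector(ndviClim), edges)
  kk <- seq_len(nb)
  argK <- which(abs(edges[-length(edges)] - argminBin) < binWidth / 2)[1]
  thrK <- which(abs(edges[-length(edges)] - thresholdBin) < binWidth / 2)[1]
  piBin <- switch(profile,
    u_shape = {
      span <- max(abs(kk - argK))
      piMin + (piMax - piMin) * ((kk - argK) / span)^2
    },
    step_jump = ifelse(kk < thrK, piLow, piHigh),
    flat = rep(piFlat, nb)
  )
  withSeed(seed, {
    lambda <- lambda0 + lambda1 * pmax(as.vector(ndviClim), 0)
    ab <- stats::rpois(nlat * nlon, lambda)
    pi_i <- rep(NA_real_, nlat * nlon)
    ok <- !is.na(binIdx)
    pi_i[ok] <- piBin[binIdx[ok]]
    th <- integer(nlat * nlon)
    th[ok] <- stats::rbinom(sum(ok), ab[ok], pi_i[ok])
    g <- function(v, nm) GridRaster(matrix(v, nlat, nlon), grid$latEdges,
                                    grid$lonEdges, nodata = -9999,
                                    name = nm)
    list(abundance = g(ab, "abundance"),
         threatened = g(th, "threatened"),
         truth = list(seed = seed, profile = profile, pi_bin = piBin,
                      bin_edges = edges, argmin_bin = argK,
                      threshold_bin = thrK, lambda0 = lambda0,
                      lambda1 = lambda1))
  })
}

#' Simulate a complete co-registered synthetic world
#'
#' Runs all four generators on one grid with sub-seeds derived from a
#' single master seed: nighttime lights with Zipf-like blob sizes, an NDVI
#' climatology spanning the vegetated range with planted city/land trends,
#' Schreiber-consistent flux fields and Poisson/binomial species layers.
#'
#' @param grid from [syntheticGrid()].
#' @param nCities,zipfExponent,slopeCity,slopeLand,residSd,years,profile
#'   passed to the generators.
#' @param seed master seed; generator sub-seeds are `seed`, `seed + 1`,
#'   `seed + 2`.
#' @param ... further arguments to [genSpecies()].
#' @return list with all layers, the city truth mask (`cityPixels`), the
#'   climatology matrix and the combined `truth` record.
#' @export
simulateWorld <- function(grid = syntheticGrid(), nCities = 50L,
                          zipfExponent = 2, slopeCity = 0.003,
                          slopeLand = 0.001, residSd = 0.01,
                          years = 1982:2013,
                          profile = "u_shape", seed = 1L, ...) {
  nlat <- length(grid$latEdges) - 1L
  nlon <- length(grid$lonEdges) - 1L
  lights <- genLights(grid, nCities = nCities, zipfExponent = zipfExponent,
                      seed = seed)
  cityPixels <- lights$light@values >= 12
  # NDVI climatology: smooth west-east gradient through the vegetated range
  clim <- matrix(rep(seq(0.05, 0.95, length.out = nlon), each = nlat),
                 nlat, nlon)
  ndvi <- genNdviSeries(grid, clim, cityPixels, slopeCity = slopeCity,
                        slopeLand = slopeLand, residSd = residSd,
                        years = years, seed = seed + 1L)
  # dryness decreasing with NDVI: wet where green
  D <- matrix(pmax(0.2, 3.5 - 3.3 * clim), nlat, nlon)
  fluxes <- genFluxes(grid, P = 1.5, D = D)
  species <- genSpecies(grid, clim, profile = profile, seed = seed + 2L,
                        ...)
  list(grid = grid, light = lights$light, cityPixels = cityPixels,
       ndviClim = clim, ndvi = ndvi$series,
       E = fluxes$E, H = fluxes$H, P = fluxes$P, D = fluxes$D,
       abundance = species$abundance, threatened = species$threatened,
       truth = list(lights = lights$truth, ndvi = ndvi$truth,
                    species = species$truth, seed = seed))
}
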