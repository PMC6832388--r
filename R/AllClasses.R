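#' @import methods
NULL

#' GridRaster: a single geographic raster layer
#'
#' A 2-D gridded field on a regular (or rectilinear) latitude/longitude grid.
#' Values are cell means registered at cell centers; the matrix is stored
#' south-to-north in rows and west-to-east in columns, whatever the order of
#' the source file. Missing cells are held as `NA` internally; the `nodata`
#' slot records the sentinel used on disk.
#'
#' @slot values numeric matrix, `nrow = length(latEdges) - 1`,
#'   `ncol = length(lonEdges) - 1`; `NA` marks nodata.
#' @slot latEdges numeric, strictly increasing cell boundaries in degrees
#'   latitude, within \[-90, 90\].
#' @slot lonEdges numeric, strictly increasing cell boundaries in degrees
#'   longitude, spanning at most 360 degrees.
#' @slot nodata numeric(1), sentinel written to file for `NA` cells.
#' @slot name character(1) layer label.
#'
#' @examples
#' r <- GridRaster(matrix(1:4, 2), latEdges = c(-1, 0, 1),
#'                 lonEdges = c(10, 11, 12), name = "toy")
#' dim(r)
#' @export
setClass("GridRaster",
  representation(
    values   = "matrix",
    latEdges = "numeric",
    lonEdges = "numeric",
    nodata   = "numeric",
    name     = "character"
  ),
  prototype(nodata = -9999, name = "")
)

setValidity("GridRaster", function(object) {
  msg <- character()
  v <- object@values
  la <- object@latEdges
  lo <- object@lonEdges
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (length(la) < 2L || any(diff(la) <= 0))
    msg <- c(msg, "latEdges must be strictly increasing with >= 2 entries")
  if (length(lo) < 2L || any(diff(lo) <= 0))
    msg <- c(msg, "lonEdges must be strictly increasing with >= 2 entries")
  if (min(la) < -90 - 1e-9 || max(la) > 90 + 1e-9)
    msg <- c(msg, "latEdges must lie within [-90, 90]")
  if (diff(range(lo)) > 360 + 1e-9)
    msg <- c(msg, "lonEdges span exceeds 360 degrees")
  if (nrow(v) != length(la) - 1L || ncol(v) != length(lo) - 1L)
    msg <- c(msg, "values shape must be (length(latEdges)-1, length(lonEdges)-1)")
  if (length(object@nodata) != 1L) msg <- c(msg, "nodata must be length 1")
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a GridRaster
#'
#' @param values numeric matrix (south-to-north rows, west-to-east columns).
#' @param latEdges,lonEdges cell edges in degrees; if given in descending
#'   order the values are flipped so the object is stored south-to-north.
#' @param nodata sentinel value; any cell equal to it becomes `NA`.
#' @param name layer label.
#' @return A [GridRaster-class] object.
#' @export
GridRaster <- function(values, latEdges, lonEdges, nodata = -9999, name = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(latEdges) > 1 && latEdges[1] > latEdges[length(latEdges)]) {
    latEdges <- rev(latEdges)
    values <- values[nrow(values):1, , drop = FALSE]
  }
  if (!is.na(nodata)) values[values == nodata] <- NA_real_
  new("GridRaster", values = values, latEdges = as.numeric(latEdges),
      lonEdges = as.numeric(lonEdges), nodata = as.numeric(nodata),
      name = as.character(name))
}

#' TimeRaster: an annual raster series on a shared grid
#'
#' @slot values numeric 3-D array `(nlat, nlon, nyear)`, `NA` = nodata.
#' @slot latEdges,lonEdges cell edges as in [GridRaster-class].
#' @slot years integer, strictly increasing.
#' @slot name character(1) label.
#' @export
setClass("TimeRaster",
  representation(
    values   = "array",
    latEdges = "numeric",
    lonEdges = "numeric",
    years    = "integer",
    name     = "character"
  ),
  prototype(name = "")
)

setValidity("TimeRaster", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3-D array")
  else {
    if (d[1] != length(object@latEdges) - 1L ||
        d[2] != length(object@lonEdges) - 1L)
      msg <- c(msg, "spatial dimensions must match the edge vectors")
    if (d[3] != length(object@years))
      msg <- c(msg, "third dimension must match length(years)")
  }
  if (length(object@years) && any(diff(object@years) <= 0L))
    msg <- c(msg, "years must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a TimeRaster
#'
#' @param values 3-D numeric array `(nlat, nlon, nyear)`.
#' @param latEdges,lonEdges cell edges in degrees.
#' @param years integer vector of years, one per layer.
#' @param name label.
#' @return A [TimeRaster-class] object.
#' @export
TimeRaster <- function(values, latEdges, lonEdges, years, name = "") {
  storage.mode(values) <- "double"
  new("TimeRaster", values = values, latEdges = as.numeric(latEdges),
      lonEdges = as.numeric(lonEdges), years = as.integer(years),
      name = as.character(name))
}

#' CityTable: labeled cities from a nighttime-light raster
#'
#' Produced by [extractCities()]. Every pixel at or above the brightness
#' threshold carries a positive component label in `labels`; background is 0.
#' Per-city records live in `cities` (`label`, `pixel_count`, `size_km2`;
#' sizes are `NA` until [citySizes()] is applied).
#'
#' @slot labels integer matrix of component labels (0 = background), on the
#'   light raster's grid.
#' @slot cities data.frame with columns `label`, `pixel_count`, `size_km2`.
#' @slot latEdges,lonEdges grid geometry of the light raster.
#' @slot dnThreshold integer brightness threshold used.
#' @slot connectivity 4 or 8.
#' @export
setClass("CityTable",
  representation(
    labels       = "matrix",
    cities       = "data.frame",
    latEdges     = "numeric",
    lonEdges     = "numeric",
    dnThreshold  = "integer",
    connectivity = "integer"
  )
)

setValidity("CityTable", function(object) {
  msg <- character()
  if (!is.integer(object@labels)) msg <- c(msg, "labels must be integer")
  need <- c("label", "pixel_count", "size_km2")
  if (!all(need %in% names(object@cities)))
    msg <- c(msg, "cities must have columns label, pixel_count, size_km2")
  if (nrow(object@cities)) {
    if (any(object@cities$label <= 0L)) msg <- c(msg, "labels must be positive")
    if (sum(object@cities$pixel_count) != sum(object@labels > 0L))
      msg <- c(msg, "pixel counts must partition the above-threshold set")
  }
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' CitySizeSpectrum: counts of cities in exponentially widening size bins
#'
#' Bin `k` (k = 1, 2, ...) covers `[base * 2^(k-2), base * 2^(k-1))` km^2,
#' with the first bin covering `(0, base)`.
#'
#' @slot binEdges numeric, strictly increasing; first entry 0.
#' @slot counts integer per-bin city counts.
#' @slot baseKm2 numeric(1), the base of the exponential binning (km^2).
#' @export
setClass("CitySizeSpectrum",
  representation(binEdges = "numeric", counts = "integer", baseKm2 = "numeric")
)

setValidity("CitySizeSpectrum", function(object) {
  msg <- character()
  if (any(diff(object@binEdges) <= 0))
    msg <- c(msg, "binEdges must be strictly increasing")
  if (length(object@counts) != length(object@binEdges) - 1L)
    msg <- c(msg, "counts must have one entry per bin")
  if (any(object@counts < 0L)) msg <- c(msg, "counts must be non-negative")
  if (object@baseKm2 <= 0) msg <- c(msg, "baseKm2 must be positive")
  if (length(msg)) msg else TRUE
})

#' StateSpaceHistogram: weighted 2-D frequency over (E, H) bins
#'
#' @slot eEdges,hEdges bin edges in m/yr water equivalent.
#' @slot weights numeric matrix `(nE, nH)` of non-negative mass.
#' @slot bandwidth numeric(1), Gaussian smoothing bandwidth in bin widths
#'   (0 = unsmoothed).
#' @slot nExcluded integer(1), pixels dropped for invalid flux or nodata.
#' @export
setClass("StateSpaceHistogram",
  representation(
    eEdges    = "numeric",
    hEdges    = "numeric",
    weights   = "matrix",
    bandwidth = "numeric",
    nExcluded = "integer"
  ),
  prototype(bandwidth = 0, nExcluded = 0L)
)

setValidity("StateSpaceHistogram", function(object) {
  msg <- character()
  if (any(diff(object@eEdges) <= 0) || any(diff(object@hEdges) <= 0))
    msg <- c(msg, "bin edges must be strictly increasing")
  if (nrow(object@weights) != length(object@eEdges) - 1L ||
      ncol(object@weights) != length(object@hEdges) - 1L)
    msg <- c(msg, "weights shape must match the bin edges")
  if (any(object@weights < -1e-12, na.rm = TRUE))
    msg <- c(msg, "weights must be non-negative")
  if (object@bandwidth < 0) msg <- c(msg, "bandwidth must be >= 0")
  if (length(msg)) msg else TRUE
})

#' TrendComparison: paired city/land NDVI trend regressions
#'
#' Annual-mean NDVI series for the city and land strata restricted to one
#' climatological-NDVI interval, their OLS fits, the city-over-land slope
#' ratio and the green/brown effect classification.
#'
#' @slot interval numeric(2), half-open climatological NDVI interval
#'   `[lo, hi)` defining the strata.
#' @slot years integer, shared year support.
#' @slot cityMeans,landMeans numeric annual area-weighted mean NDVI.
#' @slot fit data.frame, one row per stratum with `slope`, `intercept`,
#'   `resid_sd`.
#' @slot ratio numeric(1), `slope_city / slope_land` (`NA` when the land
#'   slope is indistinguishable from zero).
#' @slot effect character(1), one of `"green"`, `"brown"`, `"indeterminate"`.
#' @export
setClass("TrendComparison",
  representation(
    interval  = "numeric",
    years     = "integer",
    cityMeans = "numeric",
    landMeans = "numeric",
    fit       = "data.frame",
    ratio     = "numeric",
    effect    = "character"
  )
)

setValidity("TrendComparison", function(object) {
  msg <- character()
  if (length(object@interval) != 2L) msg <- c(msg, "interval must be length 2")
  n <- length(object@years)
  if (length(object@cityMeans) != n || length(object@landMeans) != n)
    msg <- c(msg, "both series must share the year support")
  if (!object@effect %in% c("green", "brown", "indeterminate"))
    msg <- c(msg, "effect must be green, brown or indeterminate")
  if (length(msg)) msg else TRUE
})
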