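#' Accessors for raster and histogram objects
#'
#' `gridValues()` returns the numeric value matrix/array, `latEdges()` and
#' `lonEdges()` the cell boundaries in degrees, `layerName()` the label and
#' `rasterYears()` the year vector of a [TimeRaster-class].
#'
#' @param x a GridRaster, TimeRaster, CityTable or StateSpaceHistogram.
#' @return the requested component.
#' @name raster-accessors
#' @aliases gridValues latEdges lonEdges layerName rasterYears
NULL

#' @rdname raster-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname raster-accessors
#' @export
setGeneric("latEdges", function(x) standardGeneric("latEdges"))
#' @rdname raster-accessors
#' @export
setGeneric("lonEdges", function(x) standardGeneric("lonEdges"))
#' @rdname raster-accessors
#' @export
setGeneric("layerName", function(x) standardGeneric("layerName"))
#' @rdname raster-accessors
#' @export
setGeneric("rasterYears", function(x) standardGeneric("rasterYears"))

setMethod("gridValues", "GridRaster", function(x) x@values)
setMethod("gridValues", "TimeRaster", function(x) x@values)
setMethod("latEdges", "GridRaster", function(x) x@latEdges)
setMethod("latEdges", "TimeRaster", function(x) x@latEdges)
setMethod("latEdges", "CityTable", function(x) x@latEdges)
setMethod("lonEdges", "GridRaster", function(x) x@lonEdges)
setMethod("lonEdges", "TimeRaster", function(x) x@lonEdges)
setMethod("lonEdges", "CityTable", function(x) x@lonEdges)
setMethod("layerName", "GridRaster", function(x) x@name)
setMethod("layerName", "TimeRaster", function(x) x@name)
setMethod("rasterYears", "TimeRaster", function(x) x@years)

#' @export
setMethod("dim", "GridRaster", function(x) dim(x@values))
#' @export
setMethod("dim", "TimeRaster", function(x) dim(x@values))

#' City accessors
#'
#' `cityInfo()` returns the per-city data.frame (`label`, `pixel_count`,
#' `size_km2`), `cityLabels()` the labeled integer raster (0 = background)
#' and `cityCount()` the number of cities.
#'
#' @param x a [CityTable-class].
#' @return see description.
#' @name city-accessors
#' @aliases cityInfo cityLabels cityCount
NULL

#' @rdname city-accessors
#' @export
setGeneric("cityInfo", function(x) standardGeneric("cityInfo"))
#' @rdname city-accessors
#' @export
setGeneric("cityLabels", function(x) standardGeneric("cityLabels"))
#' @rdname city-accessors
#' @export
setGeneric("cityCount", function(x) standardGeneric("cityCount"))

setMethod("cityInfo", "CityTable", function(x) x@cities)
setMethod("cityLabels", "CityTable", function(x) x@labels)
setMethod("cityCount", "CityTable", function(x) nrow(x@cities))

#' Histogram accessors
#'
#' `histWeights()` returns the weight matrix, `histMass()` its total mass,
#' `eEdges()`/`hEdges()` the bin boundaries in m/yr.
#'
#' @param x a [StateSpaceHistogram-class].
#' @return see description.
#' @name histogram-accessors
#' @aliases histWeights histMass eEdges hEdges
NULL

#' @rdname histogram-accessors
#' @export
setGeneric("histWeights", function(x) standardGeneric("histWeights"))
#' @rdname histogram-accessors
#' @export
setGeneric("histMass", function(x) standardGeneric("histMass"))
#' @rdname histogram-accessors
#' @export
setGeneric("eEdges", function(x) standardGeneric("eEdges"))
#' @rdname histogram-accessors
#' @export
setGeneric("hEdges", function(x) standardGeneric("hEdges"))

setMethod("histWeights", "StateSpaceHistogram", function(x) x@weights)
setMethod("histMass", "StateSpaceHistogram", function(x) sum(x@weights))
setMethod("eEdges", "StateSpaceHistogram", function(x) x@eEdges)
setMethod("hEdges", "StateSpaceHistogram", function(x) x@hEdges)

#' Trend accessors
#'
#' `trendRatio()` returns the city-over-land slope ratio (`NA` when the land
#' slope is indistinguishable from zero), `trendEffect()` the classification
#' and `trendFit()` the per-stratum OLS table.
#'
#' @param x a [TrendComparison-class].
#' @return see description.
#' @name trend-accessors
#' @aliases trendRatio trendEffect trendFit
NULL

#' @rdname trend-accessors
#' @export
setGeneric("trendRatio", function(x) standardGeneric("trendRatio"))
#' @rdname trend-accessors
#' @export
setGeneric("trendEffect", function(x) standardGeneric("trendEffect"))
#' @rdname trend-accessors
#' @export
setGeneric("trendFit", function(x) standardGeneric("trendFit"))

setMethod("trendRatio", "TrendComparison", function(x) x@ratio)
setMethod("trendEffect", "TrendComparison", function(x) x@effect)
setMethod("trendFit", "TrendComparison", function(x) x@fit)

setMethod("show", "GridRaster", function(object) {
  d <- dim(object@values)
  cat(sprintf("GridRaster \"%s\": %d x %d cells\n", object@name, d[1], d[2]))
  cat(sprintf("  lat [%g, %g]  lon [%g, %g]\n",
              min(object@latEdges), max(object@latEdges),
              min(object@lonEdges), max(object@lonEdges)))
  v <- object@values
  cat(sprintf("  valid cells: %d/%d  range [%g, %g]\n",
              sum(!is.na(v)), length(v),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(NULL)
})

setMethod("show", "TimeRaster", function(object) {
  d <- dim(object@values)
  cat(sprintf("TimeRaster \"%s\": %d x %d cells, %d years (%d-%d)\n",
              object@name, d[1], d[2], d[3],
              min(object@years), max(object@years)))
  invisible(NULL)
})

setMethod("show", "CityTable", function(object) {
  cat(sprintf("CityTable: %d cities (DN >= %d, %d-connectivity)\n",
              nrow(object@cities), object@dnThreshold, object@connectivity))
  if (nrow(object@cities)) {
    cat(sprintf("  lighted pixels: %d; sizes %s\n",
                sum(object@cities$pixel_count),
                if (all(is.na(object@cities$size_km2))) "unset (run citySizes)"
                else sprintf("[%.3g, %.3g] km^2",
                             min(object@cities$size_km2, na.rm = TRUE),
                             max(object@cities$size_km2, na.rm = TRUE))))
  }
  invisible(NULL)
})

setMethod("show", "CitySizeSpectrum", function(object) {
  cat(sprintf("CitySizeSpectrum: base %g km^2, %d bins, %d cities\n",
              object@baseKm2, length(object@counts), sum(object@counts)))
  invisible(NULL)
})

setMethod("show", "StateSpaceHistogram", function(object) {
  cat(sprintf(
    "StateSpaceHistogram: %d x %d (E, H) bins, mass %g%s, %d pixels excluded\n",
    nrow(object@weights), ncol(object@weights), sum(object@weights),
    if (object@bandwidth > 0)
      sprintf(" (smoothed, bandwidth %g bins)", object@bandwidth) else "",
    object@nExcluded))
  invisible(NULL)
})

setMethod("show", "TrendComparison", function(object) {
  cat(sprintf("TrendComparison over NDVI [%g, %g), %d years\n",
              object@interval[1], object@interval[2], length(object@years)))
  print(object@fit)
  cat(sprintf("  slope ratio city/land: %s; effect: %s\n",
              if (is.na(object@ratio)) "undefined"
              else sprintf("%.3f", object@ratio), object@effect))
  invisible(NULL)
})

#' @export
setMethod("as.data.frame", "CityTable",
          function(x, ...) x@cities)

#' @export
setMethod("as.data.frame", "CitySizeSpectrum", function(x, ...) {
  data.frame(bin_lo_km2 = x@binEdges[-length(x@binEdges)],
             bin_hi_km2 = x@binEdges[-1],
             n_cities = x@counts)
})

#' @export
setMethod("as.data.frame", "StateSpaceHistogram", function(x, ...) {
  nE <- length(x@eEdges) - 1L
  nH <- length(x@hEdges) - 1L
  data.frame(
    E_lo = rep(x@eEdges[-(nE + 1L)], times = nH),
    E_hi = rep(x@eEdges[-1L], times = nH),
    H_lo = rep(x@hEdges[-(nH + 1L)], each = nE),
    H_hi = rep(x@hEdges[-1L], each = nE),
    weight = as.vector(x@weights)
  )
})

#' @export
setMethod("as.data.frame", "TrendComparison", function(x, ...) {
  data.frame(
    interval_lo = x@interval[1], interval_hi = x@interval[2],
    slope_city = x@fit["city", "slope"],
    slope_land = x@fit["land", "slope"],
    ratio = x@ratio, effect = x@effect
  )
})
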