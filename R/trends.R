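#' Annual area-weighted stratum mean NDVI
#'
#' For each year, the area-weighted mean NDVI over the pixels of a stratum
#' whose climatological NDVI lies in a half-open interval `[lo, hi)`. The
#' stratum is fixed over time (membership from the climatology, not from
#' per-year values).
#'
#' @param series a [TimeRaster-class] of annual NDVI.
#' @param mask logical matrix of stratum membership.
#' @param interval numeric(2) climatological-NDVI interval `[lo, hi)`;
#'   `NULL` (default `c(-Inf, Inf)`) disables the restriction.
#' @param ndviClim optional [GridRaster-class] climatology; computed from
#'   the series when omitted.
#' @param areas optional pixel-area raster.
#' @return data.frame with columns `year`, `mean_ndvi`.
#' @export
annualStratumMean <- function(series, mask, interval = NULL,
                              ndviClim = NULL, areas = NULL) {
  stopifnot(is(series, "TimeRaster"))
  if (is.null(ndviClim)) ndviClim <- climatology(series)
  if (is.null(areas)) areas <- pixelAreaKm2(series)
  if (is.null(interval)) interval <- c(-Inf, Inf)
  clim <- ndviClim@values
  sel <- mask & !is.na(clim) & clim >= interval[1] & clim < interval[2]
  if (!any(sel))
    stop(sprintf("empty selection: no stratum pixels with NDVI in [%g, %g)",
                 interval[1], interval[2]))
  a <- areas@values[sel]
  means <- vapply(seq_along(series@years), function(k) {
    v <- series@values[, , k][sel]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * a[ok]) / sum(a[ok])
  }, numeric(1))
  data.frame(year = series@years, mean_ndvi = means)
}

#' Ordinary least-squares trend of an annual series
#'
#' @param table data.frame with columns `year` and `mean_ndvi` (from
#'   [annualStratumMean()]); at least 3 non-missing years.
#' @return list with `slope` (NDVI/yr), `intercept` (NDVI at year 0) and
#'   `resid_sd` (residual standard deviation).
#' @export
linearTrend <- function(table) {
  tab <- table[!is.na(table$mean_ndvi), , drop = FALSE]
  if (nrow(tab) < 3L) stop("need at least 3 years for a trend")
  fit <- stats::lm(mean_ndvi ~ year, data = tab)
  cf <- stats::coef(fit)
  list(slope = unname(cf["year"]), intercept = unname(cf["(Intercept)"]),
       resid_sd = stats::sd(stats::residuals(fit)))
}

#' Compare city and land greenness trends
#'
#' Fits the annual-mean NDVI trend for the city stratum and for land (city
#' plus non-city) within one climatological-NDVI interval, forms the
#' city-over-land slope ratio and classifies the city effect:
#'
#' * `green` - the city slope is positive and at least `greenRatioMin`
#'   times the land slope (cities greening much faster than land);
#' * `brown` - the ratio is within `brownBand` of 1 (city and land trends
#'   indistinguishable) or the city slope is non-positive;
#' * `indeterminate` - anything else.
#'
#' When the land slope is below `slopeEps` in magnitude the ratio is
#' undefined (`NA`) and the effect is decided on the slopes alone.
#'
#' @param series a [TimeRaster-class] of annual NDVI.
#' @param cityStratum,landStratum logical matrices of stratum membership
#'   (land should contain the city cells).
#' @param interval numeric(2) climatological-NDVI interval `[lo, hi)`.
#' @param ndviClim,areas optional precomputed climatology / areas.
#' @param greenRatioMin minimum city/land slope ratio for `green`
#'   (default 2).
#' @param brownBand half-width of the ratio band around 1 for `brown`
#'   (default 0.25).
#' @param slopeEps land-slope magnitude below which the ratio is undefined
#'   (default 1e-6 NDVI/yr).
#' @return A [TrendComparison-class].
#' @export
compareTrends <- function(series, cityStratum, landStratum,
                          interval = c(-Inf, Inf), ndviClim = NULL,
                          areas = NULL, greenRatioMin = 2,
                          brownBand = 0.25, slopeEps = 1e-6) {
  if (is.null(ndviClim)) ndviClim <- climatology(series)
  if (is.null(areas)) areas <- pixelAreaKm2(series)
  cityTab <- annualStratumMean(series, cityStratum, interval, ndviClim,
                               areas)
  landTab <- annualStratumMean(series, landStratum, interval, ndviClim,
                               areas)
  fc <- linearTrend(cityTab)
  fl <- linearTrend(landTab)
  ratio <- if (abs(fl$slope) < slopeEps) NA_real_ else fc$slope / fl$slope
  effect <- if (fc$slope <= 0) "brown"
            else if (!is.na(ratio) && ratio >= greenRatioMin) "green"
            else if (!is.na(ratio) && abs(ratio - 1) <= brownBand) "brown"
            else if (is.na(ratio)) "green"  # city greens, land flat
            else "indeterminate"
  fit <- data.frame(
    slope = c(fc$slope, fl$slope),
    intercept = c(fc$intercept, fl$intercept),
    resid_sd = c(fc$resid_sd, fl$resid_sd),
    row.names = c("city", "land")
  )
  new("TrendComparison", interval = as.numeric(interval),
      years = as.integer(cityTab$year), cityMeans = cityTab$mean_ndvi,
      landMeans = landTab$mean_ndvi, fit = fit, ratio = ratio,
      effect = effect)
}
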