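#' Threatened-species indicator
#'
#' The ratio of threatened-species count to species abundance. Using the
#' ratio corrects the raw threatened count for the area/population effect:
#' regions (or bins) with more habitat carry more species and hence more
#' threatened species, regardless of any extra pressure. Cells with zero
#' abundance are masked (`NA`), never silently divided.
#'
#' @param threatened,abundance non-negative counts (vectors, matrices or
#'   co-registered [GridRaster-class] values).
#' @return `threatened / abundance`, `NA` where `abundance == 0`.
#' @examples
#' threatenedIndicator(5, 50)    # 0.1
#' @export
threatenedIndicator <- function(threatened, abundance) {
  if (is(threatened, "GridRaster")) threatened <- threatened@values
  if (is(abundance, "GridRaster")) abundance <- abundance@values
  if (any(threatened < 0, na.rm = TRUE) || any(abundance < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  out <- threatened / abundance
  zero <- !is.na(abundance) & abundance == 0
  if (any(zero)) {
    out[zero] <- NA_real_
    message(sum(zero), " cell(s) with zero abundance masked")
  }
  out
}

#' Coefficient of interannual NDVI variability
#'
#' Per-pixel ratio of the standard deviation of annual NDVI to its
#' climatological mean. The standard deviation uses population
#' normalization (divide by n) by default. Pixels with fewer than
#' `minYears` valid years, or with non-positive mean, are masked.
#'
#' @param series a [TimeRaster-class] of annual NDVI.
#' @param minYears minimum valid years per pixel (default 3).
#' @param ddof delta degrees of freedom for the SD (0 = population,
#'   1 = sample).
#' @return A [GridRaster-class] named `"ndvi_cv"`.
#' @export
coefficientOfVariability <- function(series, minYears = 3L, ddof = 0L) {
  stopifnot(is(series, "TimeRaster"))
  v <- series@values
  n <- apply(!is.na(v), c(1, 2), sum)
  mu <- apply(v, c(1, 2), mean, na.rm = TRUE)
  sd1 <- apply(v, c(1, 2), stats::sd, na.rm = TRUE)     # ddof = 1
  sdv <- if (ddof == 0L) sd1 * sqrt(pmax(n - 1L, 0) / pmax(n, 1L)) else sd1
  cv <- sdv / mu
  bad <- n < minYears | is.na(mu) | mu <= 0
  if (any(n < minYears & n > 0L))
    warning(sum(n < minYears & n > 0L),
            " pixel(s) with fewer than ", minYears, " years masked")
  cv[bad] <- NA_real_
  GridRaster(cv, series@latEdges, series@lonEdges, nodata = -9999,
             name = "ndvi_cv")
}

#' Climatological mean of an annual series
#'
#' @param series a [TimeRaster-class].
#' @return A [GridRaster-class] of per-pixel means over years (`NA` where
#'   all years are missing).
#' @export
climatology <- function(series) {
  stopifnot(is(series, "TimeRaster"))
  mu <- apply(series@values, c(1, 2), mean, na.rm = TRUE)
  mu[!is.finite(mu)] <- NA_real_
  GridRaster(mu, series@latEdges, series@lonEdges, nodata = -9999,
             name = paste0(series@name, "_clim"))
}

#' City / non-city / land stratum masks
#'
#' Converts fractional city cover into the three analysis strata. A cell is
#' a city cell when its cover exceeds `cutoff` (default 0.5); land is the
#' union of city and non-city cells, so `city + non_city = land` holds
#' everywhere by construction.
#'
#' @param cityCover a [GridRaster-class] of fractional cover in \[0, 1\]
#'   (from [cityMask()]); `NA` cover counts as non-city where the domain is
#'   valid.
#' @param validMask optional logical matrix restricting the land domain
#'   (default: all cells).
#' @param cutoff city threshold on the cover fraction.
#' @return list of logical matrices `city`, `non_city`, `land`.
#' @export
stratumMasks <- function(cityCover, validMask = NULL, cutoff = 0.5) {
  stopifnot(is(cityCover, "GridRaster"))
  cov <- cityCover@values
  land <- if (is.null(validMask)) matrix(TRUE, nrow(cov), ncol(cov))
          else validMask
  city <- land & !is.na(cov) & cov > cutoff
  list(city = city, non_city = land & !city, land = land)
}

ndviBinEdges <- function(binWidth = 0.1, top = 1) {
  e <- seq(0, top, by = binWidth)
  if (e[length(e)] < top) e <- c(e, top)
  round(e, 9)  # exact decimal edges (0.3, not 0.30000000000000004)
}

# Assign NDVI values to half-open [T, T + width) bins; the topmost bin is
# closed above so NDVI = 1 is kept. Returns NA for NDVI outside [0, top].
ndviBinIndex <- function(ndvi, edges) {
  k <- findInterval(ndvi, edges, rightmost.closed = TRUE)
  k[!is.na(ndvi) & (ndvi < 0 | ndvi > edges[length(edges)])] <- NA_integer_
  k[!is.na(k) & k == 0L] <- NA_integer_
  k
}

#' NDVI-conditioned statistics for one stratum
#'
#' Aggregates species abundance, threatened counts, the threatened-species
#' indicator and the NDVI-variability coefficient over half-open
#' climatological-NDVI bins `[T, T + width)` within a stratum. The
#' indicator is the ratio of bin sums (threatened sum / abundance sum), not
#' a mean of per-pixel ratios, so the area/population effect cancels; the
#' variability coefficient is area-weighted. Negative NDVI is excluded as
#' non-vegetated. Empty bins are retained with masked statistics.
#'
#' @param ndviClim [GridRaster-class] climatological NDVI.
#' @param abundance,threatened [GridRaster-class] species-count layers.
#' @param cv optional [GridRaster-class] variability coefficient
#'   ([coefficientOfVariability()]).
#' @param mask logical matrix selecting the stratum cells.
#' @param areas optional [GridRaster-class] pixel areas (default computed).
#' @param binWidth NDVI bin width (default 0.1).
#' @param stratum label stored in the output.
#' @return data.frame with one row per bin: `bin_lo`, `bin_hi`,
#'   `abundance`, `threatened`, `indicator`, `cv`, `area_km2`, `n_pixels`,
#'   `stratum`.
#' @export
binStats <- function(ndviClim, abundance, threatened, cv = NULL, mask,
                     areas = NULL, binWidth = 0.1, stratum = "land") {
  stopifnot(is(ndviClim, "GridRaster"))
  d <- dim(ndviClim@values)
  if (is.null(areas)) areas <- pixelAreaKm2(ndviClim)
  for (r in list(abundance, threatened, areas))
    if (!identical(dim(r@values), d)) stop("layers are not co-registered")
  if (!is.null(cv) && !identical(dim(cv@values), d))
    stop("layers are not co-registered")
  edges <- ndviBinEdges(binWidth)
  nb <- length(edges) - 1L
  k <- ndviBinIndex(as.vector(ndviClim@values), edges)
  sel <- as.vector(mask) & !is.na(k)
  ab <- as.vector(abundance@values); th <- as.vector(threatened@values)
  a <- as.vector(areas@values)
  cvv <- if (is.null(cv)) rep(NA_real_, length(a)) else as.vector(cv@values)

  sumBy <- function(x, w = NULL, select = sel) {
    out <- rep(0, nb)
    use <- select & !is.na(x)
    if (any(use)) {
      s <- rowsum(if (is.null(w)) x[use] else (x * w)[use], group = k[use])
      out[as.integer(rownames(s))] <- s[, 1]
    }
    out
  }
  abS <- sumBy(ab)
  thS <- sumBy(th)
  areaS <- sumBy(a)
  nPix <- sumBy(rep(1, length(a)))
  cvNum <- sumBy(ifelse(is.na(cvv), NA, cvv), w = a)
  cvDen <- sumBy(ifelse(is.na(cvv), NA_real_, a))
  ind <- ifelse(abS > 0, thS / abS, NA_real_)
  cvM <- ifelse(cvDen > 0, cvNum / cvDen, NA_real_)
  empty <- nPix == 0
  ind[empty] <- NA_real_; cvM[empty] <- NA_real_
  data.frame(
    bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1L],
    abundance = abS, threatened = thS, indicator = ind, cv = cvM,
    area_km2 = areaS, n_pixels = as.integer(nPix),
    stratum = stratum
  )
}

#' Fraction of region area per NDVI bin
#'
#' The area of a region falling in each NDVI bin `[T, T + width)` divided
#' by the total region area. The fractions over the bins plus the
#' out-of-range remainder (NDVI < 0 or missing) sum to 1.
#'
#' @param ndviClim [GridRaster-class] climatological NDVI.
#' @param regionMask logical matrix selecting the region.
#' @param areas optional pixel-area raster.
#' @param binWidth NDVI bin width.
#' @return list with `bins` (data.frame `bin_lo`, `bin_hi`, `fraction`) and
#'   `out_of_range` (scalar remainder fraction).
#' @export
ndviPercentage <- function(ndviClim, regionMask, areas = NULL,
                           binWidth = 0.1) {
  stopifnot(is(ndviClim, "GridRaster"))
  if (is.null(areas)) areas <- pixelAreaKm2(ndviClim)
  sel <- as.vector(regionMask)
  a <- as.vector(areas@values)
  total <- sum(a[sel])
  if (!any(sel) || total <= 0) stop("empty region")
  edges <- ndviBinEdges(binWidth)
  nb <- length(edges) - 1L
  k <- ndviBinIndex(as.vector(ndviClim@values), edges)
  use <- sel & !is.na(k)
  frac <- rep(0, nb)
  if (any(use)) {
    s <- rowsum(a[use], group = k[use])
    frac[as.integer(rownames(s))] <- s[, 1] / total
  }
  list(bins = data.frame(bin_lo = edges[-(nb + 1L)], bin_hi = edges[-1L],
                         fraction = frac),
       out_of_range = 1 - sum(frac))
}

#' Fraction of city area per NDVI bin
#'
#' Same construction as [ndviPercentage()] but the region is the lighted
#' city area: city area within each NDVI bin over total city area.
#'
#' @param ndviClim [GridRaster-class] climatological NDVI.
#' @param cityMask logical matrix of city cells (e.g.
#'   `stratumMasks(...)$city`).
#' @param areas optional pixel-area raster.
#' @param binWidth NDVI bin width.
#' @return As [ndviPercentage()].
#' @export
cityPercentage <- function(ndviClim, cityMask, areas = NULL,
                           binWidth = 0.1) {
  if (!any(cityMask)) stop("zero city area")
  ndviPercentage(ndviClim, cityMask, areas = areas, binWidth = binWidth)
}

#' Urbanization-and-vertebrates summary table
#'
#' Reproduces the structure of a country-versus-globe urbanization summary:
#' for each region, the land-area percentage of the global land area, the
#' per-taxon (and total) abundance and threatened percentages of the global
#' totals, the city/non-city percentages of the region's land, and the
#' per-taxon percentage of threatened individuals inside versus outside
#' cities (rows sum to 100 within each taxon).
#'
#' @param regions named list of logical matrices (region land masks); must
#'   include an entry covering the whole domain (named `"global"`) or one
#'   is added as the union of all cells.
#' @param abundance,threatened named lists of [GridRaster-class] count
#'   layers, one per taxon (e.g. amphibian, birds, mammal).
#' @param cityStratum logical matrix of city cells.
#' @param areas optional pixel-area raster.
#' @return data.frame, one row per region x taxon (plus `total` rows), with
#'   columns `region`, `taxon`, `land_area_pct`, `abundance_pct`,
#'   `threatened_pct`, `city_pct`, `non_city_pct`, `threatened_in_city_pct`,
#'   `threatened_out_city_pct`.
#' @export
table1Summary <- function(regions, abundance, threatened, cityStratum,
                          areas = NULL) {
  stopifnot(is.list(regions), is.list(abundance), is.list(threatened))
  if (!length(abundance) || !identical(sort(names(abundance)),
                                       sort(names(threatened))))
    stop("abundance and threatened must be named lists over the same taxa")
  ref <- abundance[[1]]
  if (is.null(areas)) areas <- pixelAreaKm2(ref)
  a <- areas@values
  if (!"global" %in% names(regions)) {
    glob <- Reduce(`|`, regions)
    regions <- c(regions, list(global = glob))
  }
  gmask <- regions$global
  gArea <- sum(a[gmask])
  taxa <- names(abundance)
  gAb <- vapply(taxa, function(t) sum(abundance[[t]]@values[gmask],
                                      na.rm = TRUE), numeric(1))
  gTh <- vapply(taxa, function(t) sum(threatened[[t]]@values[gmask],
                                      na.rm = TRUE), numeric(1))
  rows <- list()
  for (rg in names(regions)) {
    m <- regions[[rg]]
    landA <- sum(a[m])
    cityA <- sum(a[m & cityStratum])
    for (t in c(taxa, "total")) {
      if (t == "total") {
        abR <- sum(vapply(taxa, function(tt)
          sum(abundance[[tt]]@values[m], na.rm = TRUE), numeric(1)))
        thR <- sum(vapply(taxa, function(tt)
          sum(threatened[[tt]]@values[m], na.rm = TRUE), numeric(1)))
        thIn <- sum(vapply(taxa, function(tt)
          sum(threatened[[tt]]@values[m & cityStratum], na.rm = TRUE),
          numeric(1)))
        gAbT <- sum(gAb); gThT <- sum(gTh)
      } else {
        abR <- sum(abundance[[t]]@values[m], na.rm = TRUE)
        thR <- sum(threatened[[t]]@values[m], na.rm = TRUE)
        thIn <- sum(threatened[[t]]@values[m & cityStratum], na.rm = TRUE)
        gAbT <- gAb[[t]]; gThT <- gTh[[t]]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, taxon = t,
        land_area_pct = 100 * landA / gArea,
        abundance = abR, threatened = thR,
        abundance_pct = if (gAbT > 0) 100 * abR / gAbT else NA_real_,
        threatened_pct = if (gThT > 0) 100 * thR / gThT else NA_real_,
        city_pct = 100 * cityA / landA,
        non_city_pct = 100 * (1 - cityA / landA),
        threatened_in_city_pct =
          if (thR > 0) 100 * thIn / thR else NA_real_,
        threatened_out_city_pct =
          if (thR > 0) 100 * (1 - thIn / thR) else NA_real_
      )
    }
  }
  do.call(rbind, rows)
}

#' City-size-conditioned greenness and threat statistics
#'
#' For each city, the area-weighted mean climatological NDVI over its
#' footprint and its threatened-species indicator (ratio of footprint sums);
#' then, per exponential size bin, the mean, median and quartiles of both.
#' Empty bins are retained with masked statistics.
#'
#' @param table a [CityTable-class] with sizes ([citySizes()]).
#' @param spectrum a [CitySizeSpectrum-class] defining the size bins.
#' @param ndviClim,abundance,threatened [GridRaster-class] layers on the
#'   city grid.
#' @param areas optional pixel-area raster.
#' @return list with `perCity` (data.frame `label`, `size_km2`,
#'   `mean_ndvi`, `indicator`) and `perBin` (data.frame of bin summaries).
#' @export
sizeConditionedStats <- function(table, spectrum, ndviClim, abundance,
                                 threatened, areas = NULL) {
  stopifnot(is(table, "CityTable"), is(spectrum, "CitySizeSpectrum"))
  if (!nrow(table@cities) || anyNA(table@cities$size_km2))
    stop("CityTable is empty or sizes are unset")
  if (is.null(areas)) areas <- pixelAreaKm2(ndviClim)
  lab <- table@labels
  pos <- lab > 0L
  g <- lab[pos]
  a <- areas@values[pos]
  nd <- ndviClim@values[pos]
  ab <- abundance@values[pos]
  th <- threatened@values[pos]
  agg <- function(x, w = NULL) {
    ok <- !is.na(x)
    out <- rep(NA_real_, max(g))
    if (any(ok)) {
      s <- rowsum(if (is.null(w)) x[ok] else (x * w)[ok], group = g[ok])
      out[as.integer(rownames(s))] <- s[, 1]
    }
    out
  }
  ndviNum <- agg(nd, w = a)
  ndviDen <- agg(ifelse(is.na(nd), NA_real_, a))
  abS <- agg(ab); thS <- agg(th)
  perCity <- data.frame(
    label = table@cities$label,
    size_km2 = table@cities$size_km2,
    mean_ndvi = (ndviNum / ndviDen)[table@cities$label],
    indicator = ifelse(!is.na(abS) & abS > 0, thS / abS,
                       NA_real_)[table@cities$label]
  )
  e <- spectrum@binEdges
  kb <- findInterval(perCity$size_km2, e)
  q <- function(x, p) {
    x <- x[!is.na(x)]
    if (length(x)) unname(stats::quantile(x, p)) else NA_real_
  }
  perBin <- do.call(rbind, lapply(seq_len(length(e) - 1L), function(k) {
    inb <- !is.na(kb) & kb == k
    data.frame(
      bin_lo_km2 = e[k], bin_hi_km2 = e[k + 1L],
      n_cities = sum(inb),
      mean_ndvi = if (any(inb)) mean(perCity$mean_ndvi[inb], na.rm = TRUE)
                  else NA_real_,
      median_ndvi = q(perCity$mean_ndvi[inb], 0.5),
      q25_ndvi = q(perCity$mean_ndvi[inb], 0.25),
      q75_ndvi = q(perCity$mean_ndvi[inb], 0.75),
      mean_indicator = if (any(inb)) mean(perCity$indicator[inb],
                                          na.rm = TRUE) else NA_real_,
      median_indicator = q(perCity$indicator[inb], 0.5),
      q25_indicator = q(perCity$indicator[inb], 0.25),
      q75_indicator = q(perCity$indicator[inb], 0.75)
    )
  }))
  list(perCity = perCity, perBin = perBin)
}

#' Global vertebrate census reference totals
#'
#' Global totals of the 2010 gridded vertebrate census layers (species
#' abundance and threatened-species counts) for the three terrestrial
#' taxa, used as reference denominators for summary tables and as inputs
#' for the global threatened-species indicator.
#'
#' @return data.frame with columns `taxon`, `abundance`, `threatened`.
#' @examples
#' cen <- vertebrateCensus()
#' sum(cen$threatened) / sum(cen$abundance)   # global indicator
#' @export
vertebrateCensus <- function() {
  data.frame(
    taxon = c("amphibian", "birds", "mammal"),
    abundance = c(283256, 4376655, 1270883),
    threatened = c(2892, 92513, 49782)
  )
}
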