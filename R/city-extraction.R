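#' Extract cities as contiguous bright pixels
#'
#' Labels spatially contiguous components of nighttime-light pixels at or
#' above a digital-number (DN) threshold. Every above-threshold pixel
#' belongs to exactly one component; connectivity is 8-neighbor by default
#' (diagonal contact joins components), 4-neighbor optionally. Components
#' never join across the +/-180 degree seam.
#'
#' @param light a [GridRaster-class] with integer DN values in \[0, 63\].
#' @param dnThreshold integer threshold in \[0, 63\]; default 12.
#' @param connectivity 8 (default) or 4.
#' @param inclusive if `TRUE` (default) pixels with `DN >= dnThreshold` are
#'   city pixels; `FALSE` uses a strict `>` comparison.
#' @return A [CityTable-class]; `size_km2` is `NA` until [citySizes()].
#' @examples
#' dn <- matrix(0L, 5, 5); dn[2:3, 2:3] <- 30L
#' ct <- extractCities(GridRaster(dn, 0:5, 0:5), dnThreshold = 12)
#' cityCount(ct)
#' @export
extractCities <- function(light, dnThreshold = 12L, connectivity = 8L,
                          inclusive = TRUE) {
  stopifnot(is(light, "GridRaster"))
  dnThreshold <- as.integer(dnThreshold)
  if (is.na(dnThreshold) || dnThreshold < 0L || dnThreshold > 63L)
    stop("dnThreshold must lie in [0, 63]")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  v <- light@values
  ok <- !is.na(v)
  if (any(v[ok] < 0 | v[ok] > 63 | v[ok] != round(v[ok])))
    stop("light values must be integers in [0, 63]")
  fg <- ok & (if (inclusive) v >= dnThreshold else v > dnThreshold)
  lab <- labelComponents(fg, connectivity)
  cities <- if (max(lab) > 0L) {
    data.frame(label = seq_len(max(lab)),
               pixel_count = as.integer(tabulate(lab[lab > 0L], max(lab))),
               size_km2 = NA_real_)
  } else {
    data.frame(label = integer(), pixel_count = integer(),
               size_km2 = numeric())
  }
  new("CityTable", labels = lab, cities = cities,
      latEdges = light@latEdges, lonEdges = light@lonEdges,
      dnThreshold = dnThreshold, connectivity = connectivity)
}

# Two-pass union-find connected-component labeling of a logical matrix.
# Returns an integer matrix with components numbered 1..k in order of first
# (column-major) appearance; background is 0.
labelComponents <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  findRoot <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  nlab <- 0L
  for (c in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (!fg[r, c]) next
      nb <- integer(0)
      if (r > 1L && fg[r - 1L, c]) nb <- c(nb, lab[r - 1L, c])
      if (c > 1L && fg[r, c - 1L]) nb <- c(nb, lab[r, c - 1L])
      if (connectivity == 8L && c > 1L) {
        if (r > 1L && fg[r - 1L, c - 1L]) nb <- c(nb, lab[r - 1L, c - 1L])
        if (r < nr && fg[r + 1L, c - 1L]) nb <- c(nb, lab[r + 1L, c - 1L])
      }
      if (!length(nb)) {
        nlab <- nlab + 1L
        parent[nlab] <- nlab
        lab[r, c] <- nlab
      } else {
        roots <- vapply(unique(nb), findRoot, integer(1))
        keep <- min(roots)
        lab[r, c] <- keep
        for (x in roots) parent[x] <- keep
      }
    }
  }
  if (nlab > 0L) {
    roots <- vapply(seq_len(nlab), findRoot, integer(1))
    # renumber roots consecutively in order of first appearance
    newid <- integer(nlab)
    newid[unique(roots)] <- seq_along(unique(roots))
    pos <- lab > 0L
    lab[pos] <- newid[roots[lab[pos]]]
  }
  lab
}

#' Attach city sizes from per-pixel areas
#'
#' `size(j) = sum of member pixel areas a_i(j)` in km^2.
#'
#' @param table a [CityTable-class].
#' @param areas a [GridRaster-class] of pixel areas on the same grid
#'   (defaults to [pixelAreaKm2()] of the table's grid).
#' @return The table with `size_km2` filled.
#' @export
citySizes <- function(table, areas = NULL) {
  stopifnot(is(table, "CityTable"))
  if (is.null(areas)) {
    g <- GridRaster(matrix(0, length(table@latEdges) - 1L,
                           length(table@lonEdges) - 1L),
                    table@latEdges, table@lonEdges)
    areas <- pixelAreaKm2(g)
  }
  stopifnot(is(areas, "GridRaster"))
  if (!isTRUE(all.equal(areas@latEdges, table@latEdges)) ||
      !isTRUE(all.equal(areas@lonEdges, table@lonEdges)))
    stop("areas raster is not on the city grid")
  if (!nrow(table@cities)) return(table)
  pos <- table@labels > 0L
  s <- rowsum(gridValues(areas)[pos], group = table@labels[pos])
  table@cities$size_km2 <- as.numeric(s[match(table@cities$label,
                                              as.integer(rownames(s))), 1])
  table
}

#' Exponential city-size spectrum
#'
#' Bins city sizes into exponentially widening bins with a base of
#' `baseKm2` km^2: the first bin covers `(0, base)` and bin k covers
#' `[base * 2^(k-1), base * 2^k)`.
#'
#' @param table a [CityTable-class] with sizes attached ([citySizes()]).
#' @param baseKm2 bin base in km^2 (default 2).
#' @return A [CitySizeSpectrum-class].
#' @export
sizeSpectrum <- function(table, baseKm2 = 2) {
  stopifnot(is(table, "CityTable"))
  if (baseKm2 <= 0) stop("baseKm2 must be positive")
  s <- table@cities$size_km2
  if (!nrow(table@cities) || anyNA(s))
    stop("CityTable is empty or sizes are unset; run citySizes() first")
  nbin <- max(1L, ceiling(log2(max(s) / baseKm2)) + 1L)
  edges <- c(0, baseKm2 * 2^(0:(nbin - 1L)))
  while (max(s) >= edges[length(edges)])
    edges <- c(edges, 2 * edges[length(edges)])
  k <- findInterval(s, edges, rightmost.closed = FALSE)  # [lo, hi) bins
  counts <- tabulate(k, length(edges) - 1L)
  new("CitySizeSpectrum", binEdges = edges, counts = as.integer(counts),
      baseKm2 = as.numeric(baseKm2))
}

#' Estimate the power-law exponent of a city-size spectrum
#'
#' For sizes following a density proportional to `size^(-s)`, counts in
#' exponentially widening bins fall off as `center^(1-s)`; the exponent is
#' recovered as `1 - slope` of the log-log regression of bin count on bin
#' geometric center. The fit is weighted by bin count (the log of a Poisson
#' count has variance approximately 1/count, so sparse tail bins would
#' otherwise dominate) and restricted to bins with at least `minCount`
#' cities.
#'
#' @param spectrum a [CitySizeSpectrum-class].
#' @param minCount smallest bin count admitted to the fit (default 5).
#' @return list with `exponent` and the log-log `slope`.
#' @export
sizeSpectrumExponent <- function(spectrum, minCount = 5L) {
  stopifnot(is(spectrum, "CitySizeSpectrum"))
  e <- spectrum@binEdges
  ctr <- sqrt(pmax(e[-length(e)], e[2] / 2) * e[-1])  # geometric centers
  use <- spectrum@counts >= minCount
  if (sum(use) < 2L) stop("need at least two bins with >= ", minCount,
                          " cities")
  n <- spectrum@counts[use]
  fit <- stats::lm(log(n) ~ log(ctr[use]), weights = n)
  slope <- unname(stats::coef(fit)[2])
  list(exponent = 1 - slope, slope = slope)
}

#' City cover as a raster
#'
#' Binary city membership on the native (fine) grid, or fractional city
#' cover on a coarser analysis grid: the area fraction of each coarse cell
#' covered by lighted city pixels.
#'
#' @param table a [CityTable-class].
#' @param targetLatEdges,targetLonEdges optional coarse-grid edges; when
#'   omitted the binary fine-grid mask is returned.
#' @return A [GridRaster-class] with values in \[0, 1\], named
#'   `"city_cover"`.
#' @export
cityMask <- function(table, targetLatEdges = NULL, targetLonEdges = NULL) {
  stopifnot(is(table, "CityTable"))
  fine <- GridRaster((table@labels > 0L) * 1.0, table@latEdges,
                     table@lonEdges, nodata = -9999, name = "city_cover")
  if (is.null(targetLatEdges)) return(fine)
  out <- aggregateFraction(fine, targetLatEdges, targetLonEdges)
  out@name <- "city_cover"
  out
}
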