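#' Bilinear resampling between lat/lon grids
#'
#' Interpolates a continuous-valued source raster to the cell centers of a
#' target grid. Cell values are treated as point values at cell centers
#' (center-to-center convention). Target centers outside the hull of source
#' centers but inside the source extent are clamped to the boundary
#' row/column (edge padding). Nodata handling follows `nodataPolicy`:
#' `"renormalize"` (default) renormalizes the bilinear weights over the
#' valid neighbors, masking only where all four are nodata;
#' `"strict"` masks a target cell whenever any contributing neighbor is
#' nodata.
#'
#' @param src a [GridRaster-class] with a continuous-valued layer.
#' @param targetLatEdges,targetLonEdges cell edges of the target grid.
#' @param nodataPolicy `"renormalize"` or `"strict"`.
#' @return A [GridRaster-class] on the target grid.
#' @examples
#' src <- GridRaster(matrix(1, 4, 4), latEdges = 0:4, lonEdges = 0:4)
#' out <- resampleBilinear(src, targetLatEdges = c(0, 2, 4),
#'                         targetLonEdges = c(0, 2, 4))
#' all(gridValues(out) == 1)
#' @export
resampleBilinear <- function(src, targetLatEdges, targetLonEdges,
                             nodataPolicy = c("renormalize", "strict")) {
  stopifnot(is(src, "GridRaster"))
  nodataPolicy <- match.arg(nodataPolicy)
  if (max(targetLatEdges) <= min(src@latEdges) ||
      min(targetLatEdges) >= max(src@latEdges) ||
      max(targetLonEdges) <= min(src@lonEdges) ||
      min(targetLonEdges) >= max(src@lonEdges))
    stop("source and target grids do not overlap")

  sc <- cellCenters(src)
  tlat <- (targetLatEdges[-1] + targetLatEdges[-length(targetLatEdges)]) / 2
  tlon <- (targetLonEdges[-1] + targetLonEdges[-length(targetLonEdges)]) / 2

  idx <- function(t, c) {
    if (length(c) == 1L) list(i = rep(1L, length(t)), w = rep(0, length(t)))
    else {
      i <- findInterval(t, c, all.inside = TRUE)
      w <- (t - c[i]) / (c[i + 1L] - c[i])
      list(i = i, w = pmin(pmax(w, 0), 1))  # clamp: edge padding outside hull
    }
  }
  ly <- idx(tlat, sc$lat)
  lx <- idx(tlon, sc$lon)

  v <- src@values
  nT <- length(tlat); mT <- length(tlon)
  acc <- matrix(0, nT, mT)      # sum of weight * value over valid neighbors
  wacc <- matrix(0, nT, mT)     # sum of weights over valid neighbors
  anyNAw <- matrix(FALSE, nT, mT)
  single <- list(i = NULL)
  for (a in 0:1) for (b in 0:1) {
    ri <- pmin(ly$i + a, nrow(v)); ci <- pmin(lx$i + b, ncol(v))
    wy <- if (a == 0) 1 - ly$w else ly$w
    wx <- if (b == 0) 1 - lx$w else lx$w
    W <- outer(wy, wx)
    sub <- v[ri, ci, drop = FALSE]
    bad <- is.na(sub)
    anyNAw <- anyNAw | (bad & W > 1e-12)
    sub[bad] <- 0
    W0 <- W; W0[bad] <- 0
    acc <- acc + W0 * sub
    wacc <- wacc + W0
  }
  out <- acc / wacc
  out[wacc <= 1e-12] <- NA_real_
  if (nodataPolicy == "strict") out[anyNAw] <- NA_real_
  GridRaster(out, targetLatEdges, targetLonEdges, nodata = src@nodata,
             name = src@name)
}

#' Spherical pixel areas in km^2
#'
#' Area of each cell as a spherical quadrilateral on a sphere of radius
#' 6371 km: `R^2 * dlambda * (sin(lat_hi) - sin(lat_lo))`. Summed over a
#' full-globe grid this reproduces the Earth surface area 4*pi*R^2 to well
#' under 0.1%.
#'
#' @param raster a GridRaster or TimeRaster supplying the geometry.
#' @return A [GridRaster-class] of per-cell areas (km^2), named
#'   `"pixel_area_km2"`.
#' @export
pixelAreaKm2 <- function(raster) {
  R <- 6371.0
  la <- raster@latEdges
  lo <- raster@lonEdges
  band <- R^2 * (sin(la[-1] * pi / 180) - sin(la[-length(la)] * pi / 180))
  dlam <- diff(lo) * pi / 180
  GridRaster(outer(band, dlam), la, lo, nodata = -9999,
             name = "pixel_area_km2")
}

#' Aggregate a fine binary/fractional field to coarse-cell fractions
#'
#' Area-weighted mean of a fine-resolution field over each coarse cell;
#' used to carry fine city masks to an analysis grid as fractional cover.
#' Fine cells are assigned to the coarse cell containing their center.
#'
#' @param fine a [GridRaster-class] (values in \[0, 1\] for cover use).
#' @param coarseLatEdges,coarseLonEdges target cell edges.
#' @return A [GridRaster-class] of area-weighted means on the coarse grid;
#'   coarse cells with no fine-cell centers are nodata.
#' @export
aggregateFraction <- function(fine, coarseLatEdges, coarseLonEdges) {
  stopifnot(is(fine, "GridRaster"))
  fc <- cellCenters(fine)
  a <- gridValues(pixelAreaKm2(fine))
  v <- fine@values
  iy <- findInterval(fc$lat, coarseLatEdges, rightmost.closed = TRUE)
  ix <- findInterval(fc$lon, coarseLonEdges, rightmost.closed = TRUE)
  nr <- length(coarseLatEdges) - 1L; nc <- length(coarseLonEdges) - 1L
  keep <- outer(iy >= 1L & iy <= nr, ix >= 1L & ix <= nc) & !is.na(v)
  cell <- outer(iy, (ix - 1L) * nr, "+")  # linear coarse index per fine cell
  num <- rep(0, nr * nc); den <- rep(0, nr * nc)
  if (any(keep)) {
    den_rs <- rowsum(a[keep], group = cell[keep])
    num_rs <- rowsum((a * v)[keep], group = cell[keep])
    ugrp <- as.integer(rownames(den_rs))
    den[ugrp] <- den_rs[, 1]
    num[ugrp] <- num_rs[, 1]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  GridRaster(matrix(out, nr, nc), coarseLatEdges, coarseLonEdges,
             nodata = -9999, name = fine@name)
}
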