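#' Convert half-day energy-flux integrals to water-equivalent fluxes
#'
#' Reanalysis surface energy fluxes delivered as half-day integrals
#' (J m^-2 per 12 h) are converted to water equivalents in m/yr using the
#' latent heat of condensation of water at 0 degrees C,
#' `L = 0.25e7 J kg^-1`, and a water density of 1000 kg m^-3:
#' `flux * 2 * 365 / (L * rho_w)`, i.e. 2.920e-7 m/yr per unit flux.
#'
#' @param flux numeric, J m^-2 per 12 h (vector, matrix or GridRaster
#'   values).
#' @return the flux in m/yr water equivalent, same shape as the input.
#' @examples
#' energyToWaterEquivalent(1)      # 2.92e-07
#' @export
energyToWaterEquivalent <- function(flux) {
  L <- 0.25e7       # J/kg, latent heat of condensation at 0 C
  rho_w <- 1000     # kg/m^3
  flux * 2 * 365 / (L * rho_w)
}

#' Schreiber's equation of state
#'
#' The evaporative fraction as a function of the dryness ratio `D = N / P`:
#' `E/P = 1 - exp(-D)`; strictly increasing from 0 at `D = 0` towards its
#' asymptote 1.
#'
#' @param D dryness ratio, `>= 0`.
#' @return `E/P` in \[0, 1).
#' @export
schreiberRatio <- function(D) {
  if (any(D < 0, na.rm = TRUE)) stop("dryness ratio D must be >= 0")
  1 - exp(-D)
}

#' Precipitation isoline in (E, H) space
#'
#' Along constant precipitation `P`, the Schreiber relation fixes the
#' sensible heat flux at `H = -P * log(1 - E/P) - E`, for `0 <= E < P`.
#'
#' @param E evapotranspiration, m/yr; `0 <= E < P` elementwise.
#' @param P precipitation, m/yr.
#' @return H in m/yr.
#' @export
precipitationIsoline <- function(E, P) {
  if (any(E < 0, na.rm = TRUE))
    stop("E must be non-negative")
  if (any(E >= P, na.rm = TRUE))
    stop("E must be below P: under the Schreiber relation evaporation ",
         "cannot reach the water supply")
  -P * log(1 - E / P) - E
}

#' Dryness isoline in (E, H) space
#'
#' Along constant dryness `D`, evapotranspiration is proportional to the
#' sensible heat flux: `E = H * (1 - exp(-D)) / (D - 1 + exp(-D))`.
#'
#' @param H sensible heat flux, m/yr, `>= 0`.
#' @param D dryness ratio, `> 0`.
#' @return E in m/yr.
#' @export
drynessIsoline <- function(H, D) {
  if (any(H < 0, na.rm = TRUE)) stop("H must be >= 0")
  if (any(D <= 0, na.rm = TRUE)) stop("D must be > 0")
  denom <- D - 1 + exp(-D)
  if (any(denom < .Machine$double.eps * 4, na.rm = TRUE))
    stop("D too close to 0: the isoline slope (1 - exp(-D)) / ",
         "(D - 1 + exp(-D)) diverges as D -> 0 (the isoline degenerates ",
         "into the H axis)")
  H * (1 - exp(-D)) / denom
}

#' Geobotanic dryness regimes
#'
#' Classifies the dryness ratio into the Budyko geobotanic zones: tundra
#' (`D < 1/3`), forest (`1/3 <= D < 1`), steppe/savanna (`1 <= D < 2`),
#' semi-desert (`2 <= D < 3`) and desert (`D >= 3`). Boundary values belong
#' to the drier (upper) class (half-open `[lo, hi)` intervals).
#'
#' @param D dryness ratio, `>= 0`.
#' @return factor with levels `tundra`, `forest`, `steppe_savanna`,
#'   `semi_desert`, `desert`.
#' @export
classifyDrynessRegime <- function(D) {
  if (any(D < 0, na.rm = TRUE)) stop("dryness ratio D must be >= 0")
  lv <- c("tundra", "forest", "steppe_savanna", "semi_desert", "desert")
  idx <- findInterval(D, c(1 / 3, 1, 2, 3)) + 1L
  factor(lv[idx], levels = lv)
}

#' Embed co-registered fields in (E, H) state space
#'
#' Builds the weighted 2-D frequency distribution over evapotranspiration
#' and sensible-heat bins: each valid pixel contributes its weight (1 for
#' number density) to the bin holding its `(E, H)` pair. Pixels with
#' `E <= 0`, `H < 0` or any nodata among E, H and the weight layer are
#' excluded and counted in the `nExcluded` diagnostic.
#'
#' @param E,H [GridRaster-class] fluxes in m/yr on a shared grid.
#' @param weights optional [GridRaster-class] of non-negative weights
#'   (e.g. NDVI, abundance, threatened counts, pixel areas); `NULL` gives
#'   number density.
#' @param eEdges,hEdges bin edges in m/yr; defaults cover \[0, 3\] in 0.1
#'   steps.
#' @return A [StateSpaceHistogram-class]. Pairs falling outside the binned
#'   range are excluded (and counted).
#' @export
embedStateSpace <- function(E, H, weights = NULL,
                            eEdges = seq(0, 3, by = 0.1),
                            hEdges = seq(0, 3, by = 0.1)) {
  stopifnot(is(E, "GridRaster"), is(H, "GridRaster"))
  if (!identical(dim(E@values), dim(H@values)))
    stop("E and H are not co-registered")
  e <- as.vector(E@values); h <- as.vector(H@values)
  w <- if (is.null(weights)) rep(1, length(e))
       else {
         stopifnot(is(weights, "GridRaster"))
         if (!identical(dim(weights@values), dim(E@values)))
           stop("weights raster is not co-registered")
         as.vector(weights@values)
       }
  valid <- !is.na(e) & !is.na(h) & !is.na(w) & e > 0 & h >= 0
  nE <- length(eEdges) - 1L; nH <- length(hEdges) - 1L
  ie <- findInterval(e[valid], eEdges, rightmost.closed = TRUE)
  ih <- findInterval(h[valid], hEdges, rightmost.closed = TRUE)
  inbin <- ie >= 1L & ie <= nE & ih >= 1L & ih <= nH
  W <- matrix(0, nE, nH)
  if (any(inbin)) {
    cellIdx <- ie[inbin] + (ih[inbin] - 1L) * nE
    mass <- rowsum(w[valid][inbin], group = cellIdx)
    W[as.integer(rownames(mass))] <- mass[, 1]
  }
  if (sum(valid) == 0L)
    warning("no valid pixels to embed; histogram is empty")
  new("StateSpaceHistogram", eEdges = as.numeric(eEdges),
      hEdges = as.numeric(hEdges), weights = W, bandwidth = 0,
      nExcluded = as.integer(length(e) - sum(valid) + sum(!inbin)))
}

#' Gaussian smoothing of a state-space histogram
#'
#' Separable Gaussian kernel smoothing with reflective boundaries;
#' reflection makes the discrete kernel mass-preserving, so the total
#' histogram mass is unchanged (to floating-point round-off). The bandwidth
#' is the kernel standard deviation in units of bins; 0 returns the input
#' unchanged.
#'
#' @param hist a [StateSpaceHistogram-class].
#' @param bandwidth numeric `>= 0`, in bin widths.
#' @return A smoothed [StateSpaceHistogram-class].
#' @export
smoothHistogram <- function(hist, bandwidth = 1) {
  stopifnot(is(hist, "StateSpaceHistogram"))
  if (bandwidth < 0) stop("bandwidth must be >= 0")
  if (bandwidth == 0) return(hist)
  half <- max(1L, ceiling(4 * bandwidth))
  k <- stats::dnorm(-half:half, sd = bandwidth)
  k <- k / sum(k)
  W <- hist@weights
  W <- apply(W, 2, reflectConvolve, kernel = k)
  W <- t(apply(W, 1, reflectConvolve, kernel = k))
  new("StateSpaceHistogram", eEdges = hist@eEdges, hEdges = hist@hEdges,
      weights = W, bandwidth = bandwidth, nExcluded = hist@nExcluded)
}

# 1-D convolution with reflective (mirror) padding; kernel length 2h+1.
reflectConvolve <- function(x, kernel) {
  n <- length(x)
  h <- (length(kernel) - 1L) %/% 2L
  idx <- c(rev(seq_len(min(h, n))), seq_len(n),
           n + 1L - seq_len(min(h, n)))
  # if h > n the mirror needs repeated folding
  if (h > n) {
    idx <- vapply(seq(1L - h, n + h), function(i) {
      while (i < 1L || i > n) {
        if (i < 1L) i <- 1L - i           # half-sample reflection at left
        if (i > n) i <- 2L * n + 1L - i   # and at right
      }
      i
    }, integer(1))
  }
  xp <- x[idx]
  out <- stats::filter(xp, kernel, sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}
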