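# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations.

# Stack-based flood fill labeling of a logical matrix (oracle for the
# union-find labeler). Returns labels in scan order of the fill seeds.
floodFillLabels <- function(fg, connectivity = 8L) {
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!fg[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (q in seq_len(nrow(nb))) {
        r <- p[1] + nb[q, 1]; c <- p[2] + nb[q, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            fg[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# TRUE when two labelings agree up to a relabeling (bijection).
sameUpToRelabel <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  pos <- a > 0L
  if (!any(pos)) return(TRUE)
  key <- paste(a[pos], b[pos])
  m <- unique(cbind(a[pos], b[pos]))
  !any(duplicated(m[, 1])) && !any(duplicated(m[, 2]))
}

# Per-point 4-neighbor bilinear interpolation oracle (scalar loop, edge
# clamped), matching the center-to-center convention.
bruteBilinear <- function(srcVals, srcLat, srcLon, tLat, tLon) {
  out <- matrix(NA_real_, length(tLat), length(tLon))
  for (i in seq_along(tLat)) for (j in seq_along(tLon)) {
    y <- tLat[i]; x <- tLon[j]
    iy <- max(1, min(findInterval(y, srcLat), length(srcLat) - 1))
    ix <- max(1, min(findInterval(x, srcLon), length(srcLon) - 1))
    if (y < srcLat[1]) { iy <- 1 }
    if (x < srcLon[1]) { ix <- 1 }
    wy <- (y - srcLat[iy]) / (srcLat[iy + 1] - srcLat[iy])
    wx <- (x - srcLon[ix]) / (srcLon[ix + 1] - srcLon[ix])
    wy <- min(max(wy, 0), 1); wx <- min(max(wx, 0), 1)
    out[i, j] <- (1 - wy) * (1 - wx) * srcVals[iy, ix] +
      (1 - wy) * wx * srcVals[iy, ix + 1] +
      wy * (1 - wx) * srcVals[iy + 1, ix] +
      wy * wx * srcVals[iy + 1, ix + 1]
  }
  out
}

# Double-loop 2-D binning oracle for the state-space embedding.
bruteBin2d <- function(e, h, w, eEdges, hEdges) {
  nE <- length(eEdges) - 1L; nH <- length(hEdges) - 1L
  M <- matrix(0, nE, nH)
  for (p in seq_along(e)) {
    if (is.na(e[p]) || is.na(h[p]) || is.na(w[p])) next
    if (e[p] <= 0 || h[p] < 0) next
    for (a in seq_len(nE)) for (b in seq_len(nH)) {
      inE <- e[p] >= eEdges[a] &&
        (e[p] < eEdges[a + 1] || (a == nE && e[p] == eEdges[a + 1]))
      inH <- h[p] >= hEdges[b] &&
        (h[p] < hEdges[b + 1] || (b == nH && h[p] == hEdges[b + 1]))
      if (inE && inH) M[a, b] <- M[a, b] + w[p]
    }
  }
  M
}

# Closed-form normal-equations OLS slope/intercept oracle.
olsClosedForm <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  list(slope = slope, intercept = yb - slope * xb)
}

# Small co-registered toy grid for hand-computed cases.
toyGrid <- function(n = 10L, latLo = 0, latHi = n, lonLo = 0, lonHi = n) {
  list(latEdges = seq(latLo, latHi, length.out = n + 1L),
       lonEdges = seq(lonLo, lonHi, length.out = n + 1L))
}
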