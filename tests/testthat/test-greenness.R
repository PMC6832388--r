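test_that("the threatened-species indicator is a guarded ratio", {
  expect_equal(threatenedIndicator(0, 50), 0)
  expect_equal(threatenedIndicator(5, 50), 0.1)
  expect_error(threatenedIndicator(-1, 10), "non-negative")
  # zero abundance is masked, never divided silently
  expect_message(out <- threatenedIndicator(c(1, 2), c(10, 0)), "masked")
  expect_equal(out[1], 0.1)
  expect_true(is.na(out[2]))

  # the global census totals give the global indicator
  cen <- vertebrateCensus()
  expect_equal(sum(cen$threatened) / sum(cen$abundance), 145187 / 5930794,
               tolerance = 1e-12)
  expect_equal(145187 / 5930794, 0.02448, tolerance = 1e-3)
})

test_that("indicator is invariant under joint count scaling", {
  set.seed(5)
  th <- matrix(rpois(25, 3), 5); ab <- matrix(rpois(25, 20) + 1, 5)
  base <- threatenedIndicator(th, ab)
  for (c in c(0.5, 2, 7))
    expect_equal(threatenedIndicator(c * th, c * ab), base,
                 tolerance = 1e-12)
})

test_that("the NDVI variability coefficient is sigma over mu", {
  g <- toyGrid(2)
  mk <- function(...) {
    layers <- list(...)
    arr <- array(NA_real_, c(2, 2, length(layers)))
    for (k in seq_along(layers)) arr[, , k] <- layers[[k]]
    TimeRaster(arr, g$latEdges, g$lonEdges, seq_len(length(layers)) + 2000)
  }
  # constant series -> 0
  tr <- mk(matrix(0.4, 2, 2), matrix(0.4, 2, 2), matrix(0.4, 2, 2))
  expect_equal(gridValues(coefficientOfVariability(tr)),
               matrix(0, 2, 2), tolerance = 1e-12)

  # {0.2, 0.4} with population sigma: 0.1 / 0.3
  tr2 <- mk(matrix(0.2, 2, 2), matrix(0.4, 2, 2))
  cv2 <- suppressWarnings(coefficientOfVariability(tr2, minYears = 2))
  expect_equal(gridValues(cv2)[1, 1], 0.1 / 0.3, tolerance = 1e-12)

  # non-positive mean is masked
  tr3 <- mk(matrix(-0.1, 2, 2), matrix(0.1, 2, 2), matrix(0, 2, 2))
  expect_true(all(is.na(gridValues(coefficientOfVariability(tr3)))))

  # too few years -> masked with a warning
  v <- array(0.5, c(2, 2, 4)); v[1, 1, 2:4] <- NA
  tr4 <- TimeRaster(v, g$latEdges, g$lonEdges, 2001:2004)
  expect_warning(cv4 <- coefficientOfVariability(tr4), "fewer than")
  expect_true(is.na(gridValues(cv4)[1, 1]))
  expect_false(is.na(gridValues(cv4)[2, 2]))
})

test_that("binStats aggregates with ratio-of-sums per NDVI bin", {
  g <- toyGrid(2)
  mkr <- function(m) GridRaster(m, g$latEdges, g$lonEdges)
  # single pixel at NDVI 0.25 -> all mass in the bin starting at 0.2
  nd <- mkr(matrix(c(0.25, NA, NA, NA), 2))
  ab <- mkr(matrix(c(10, 0, 0, 0), 2))
  th <- mkr(matrix(c(1, 0, 0, 0), 2))
  bs <- binStats(nd, ab, th, mask = matrix(TRUE, 2, 2))
  expect_equal(bs$abundance[bs$bin_lo == 0.2], 10)
  expect_equal(sum(bs$abundance), 10)

  # two pixels in one bin: indicator = (1 + 5) / (10 + 30), not mean ratio
  nd2 <- mkr(matrix(c(0.31, 0.39, NA, NA), 2))
  ab2 <- mkr(matrix(c(10, 30, 0, 0), 2))
  th2 <- mkr(matrix(c(1, 5, 0, 0), 2))
  bs2 <- binStats(nd2, ab2, th2, mask = matrix(TRUE, 2, 2))
  expect_equal(bs2$indicator[bs2$bin_lo == 0.3], 6 / 40, tolerance = 1e-12)

  # empty bins are retained with masked statistics
  expect_identical(nrow(bs2), 10L)
  expect_true(is.na(bs2$indicator[bs2$bin_lo == 0.7]))
})

test_that("planted U-shape argmin bin is recovered from bin stats", {
  grid <- syntheticGrid(120, 120)
  clim <- matrix(rep(seq(0.05, 0.95, length.out = 120), each = 120),
                 120, 120)
  sp <- genSpecies(grid, clim, profile = "u_shape", argminBin = 0.3,
                   seed = 77)
  nd <- GridRaster(clim, grid$latEdges, grid$lonEdges)
  bs <- binStats(nd, sp$abundance, sp$threatened,
                 mask = matrix(TRUE, 120, 120))
  expect_equal(bs$bin_lo[which.min(bs$indicator)], 0.3)
})

test_that("stratum additivity holds exactly: city + non_city = land", {
  w <- simulateWorld(grid = syntheticGrid(60, 60), nCities = 12, seed = 13)
  nd <- GridRaster(w$ndviClim, w$grid$latEdges, w$grid$lonEdges)
  ct <- citySizes(extractCities(w$light))
  masks <- stratumMasks(cityMask(ct))
  get <- function(s) binStats(nd, w$abundance, w$threatened,
                              mask = masks[[s]], stratum = s)
  land <- get("land"); city <- get("city"); non <- get("non_city")
  expect_identical(city$abundance + non$abundance, land$abundance)
  expect_identical(city$threatened + non$threatened, land$threatened)
  expect_equal(city$area_km2 + non$area_km2, land$area_km2,
               tolerance = 1e-9)
})

test_that("ndviPercentage partitions region area", {
  g <- toyGrid(2)
  mkr <- function(m) GridRaster(m, g$latEdges, g$lonEdges)
  # uniform NDVI 0.35 -> all mass in bin starting 0.3
  p <- ndviPercentage(mkr(matrix(0.35, 2, 2)), matrix(TRUE, 2, 2))
  expect_equal(p$bins$fraction[p$bins$bin_lo == 0.3], 1)
  expect_equal(p$out_of_range, 0, tolerance = 1e-12)

  # two equal-area values on the same latitude band -> 0.5 / 0.5
  nd <- mkr(matrix(c(0.15, 0.15, 0.45, 0.45), 2))
  p2 <- ndviPercentage(nd, matrix(TRUE, 2, 2))
  expect_equal(p2$bins$fraction[p2$bins$bin_lo == 0.1], 0.5,
               tolerance = 1e-12)
  expect_equal(p2$bins$fraction[p2$bins$bin_lo == 0.4], 0.5,
               tolerance = 1e-12)

  # fractions + out-of-range remainder = 1 even with negative NDVI
  nd3 <- mkr(matrix(c(-0.2, 0.5, NA, 0.8), 2))
  p3 <- ndviPercentage(nd3, matrix(TRUE, 2, 2))
  expect_equal(sum(p3$bins$fraction) + p3$out_of_range, 1,
               tolerance = 1e-12)
  expect_gt(p3$out_of_range, 0)

  expect_error(ndviPercentage(nd3, matrix(FALSE, 2, 2)), "empty region")

  # near-uniform climatology gives near-uniform bin fractions
  grid <- syntheticGrid(50, 50)
  climU <- matrix(rep(seq(0.001, 0.999, length.out = 50), each = 50), 50)
  pu <- ndviPercentage(GridRaster(climU, grid$latEdges, grid$lonEdges),
                       matrix(TRUE, 50, 50))
  expect_true(all(abs(pu$bins$fraction - 0.1) < 0.03))
})

test_that("cityPercentage restricts the partition to city area", {
  g <- toyGrid(2)
  mkr <- function(m) GridRaster(m, g$latEdges, g$lonEdges)
  nd <- mkr(matrix(c(0.25, 0.25, 0.55, 0.55), 2))
  city <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2)
  p <- cityPercentage(nd, city)
  expect_equal(p$bins$fraction[p$bins$bin_lo == 0.2], 0.5, tolerance = 1e-12)
  expect_equal(p$bins$fraction[p$bins$bin_lo == 0.5], 0.5, tolerance = 1e-12)
  # all city pixels in one bin -> 1 there
  p1 <- cityPercentage(nd, matrix(c(TRUE, TRUE, FALSE, FALSE), 2))
  expect_equal(p1$bins$fraction[p1$bins$bin_lo == 0.2], 1, tolerance = 1e-12)
  expect_error(cityPercentage(nd, matrix(FALSE, 2, 2)), "zero city area")
})

test_that("the summary table reproduces planted two-region arithmetic", {
  g <- toyGrid(2, latLo = -1, latHi = 1)  # equator-symmetric: equal areas
  mkr <- function(m) GridRaster(m, g$latEdges, g$lonEdges)
  # region A = west column, region B = east column; city = one A-cell
  regA <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  regB <- !regA
  city <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2)
  ab <- mkr(matrix(c(10, 30, 40, 20), 2))
  th <- mkr(matrix(c(2, 4, 6, 8), 2))
  tb <- table1Summary(regions = list(A = regA, B = regB),
                      abundance = list(vert = ab),
                      threatened = list(vert = th), cityStratum = city)
  rowA <- tb[tb$region == "A" & tb$taxon == "vert", ]
  expect_equal(rowA$abundance_pct, 100 * 40 / 100, tolerance = 1e-9)
  expect_equal(rowA$threatened_pct, 100 * 6 / 20, tolerance = 1e-9)
  expect_equal(rowA$threatened_in_city_pct, 100 * 2 / 6, tolerance = 1e-9)
  expect_equal(rowA$land_area_pct, 50, tolerance = 1e-9)
  # in/out percentages always sum to 100
  expect_equal(tb$threatened_in_city_pct + tb$threatened_out_city_pct,
               rep(100, nrow(tb)), tolerance = 1e-9)

  # all species inside cities -> in/out = 100/0
  th2 <- mkr(matrix(c(5, 0, 0, 0), 2))
  tb2 <- table1Summary(regions = list(A = regA | regB),
                       abundance = list(vert = ab),
                       threatened = list(vert = th2), cityStratum = city)
  r <- tb2[tb2$region == "A" & tb2$taxon == "vert", ]
  expect_equal(r$threatened_in_city_pct, 100)
  expect_equal(r$threatened_out_city_pct, 0)
})

test_that("size-conditioned statistics follow a planted monotone law", {
  # indicator decreasing in size: larger cities get lower pi
  grid <- syntheticGrid(80, 80)
  set.seed(19)
  dn <- matrix(0L, 80, 80)
  sizes <- c(1, 2, 4, 8, 16, 32)
  origins <- cbind(seq(5, 75, length.out = 6), seq(5, 70, length.out = 6))
  for (k in seq_along(sizes)) {
    r0 <- round(origins[k, 1]); c0 <- round(origins[k, 2])
    w <- ceiling(sqrt(sizes[k]))
    px <- 0L
    for (dc in 0:(w - 1)) for (dr in 0:(w - 1)) {
      if (px < sizes[k]) { dn[r0 + dr, c0 + dc] <- 40L; px <- px + 1L }
    }
  }
  light <- GridRaster(dn, grid$latEdges, grid$lonEdges)
  ct <- citySizes(extractCities(light))
  sp <- sizeSpectrum(ct, baseKm2 = 2)
  nd <- GridRaster(matrix(0.5, 80, 80), grid$latEdges, grid$lonEdges)
  # abundance 1000/pixel; threatened proportional to 1/pixel_count
  abm <- matrix(1000, 80, 80)
  thm <- matrix(0, 80, 80)
  lab <- cityLabels(ct)
  info <- cityInfo(ct)
  for (j in info$label)
    thm[lab == j] <- round(1000 * 0.2 / info$pixel_count[j])
  stats <- sizeConditionedStats(ct, sp,
                                nd,
                                GridRaster(abm, grid$latEdges,
                                           grid$lonEdges),
                                GridRaster(thm, grid$latEdges,
                                           grid$lonEdges))
  pb <- stats$perBin[stats$perBin$n_cities > 0, ]
  expect_true(all(diff(pb$mean_indicator) <= 1e-12))

  # quartiles match an independent sort-based oracle
  set.seed(23)
  x <- stats$perCity$indicator
  w2 <- simulateWorld(grid = syntheticGrid(150, 150), nCities = 200,
                      seed = 29)
  ct2 <- citySizes(extractCities(w2$light))
  sp2 <- sizeSpectrum(ct2)
  nd2 <- GridRaster(w2$ndviClim, w2$grid$latEdges, w2$grid$lonEdges)
  st2 <- sizeConditionedStats(ct2, sp2, nd2, w2$abundance, w2$threatened)
  kb <- findInterval(st2$perCity$size_km2, sp2@binEdges)
  sortQuartile <- function(v, p) {
    # type-7 quantile by explicit sorting and interpolation
    v <- sort(v[!is.na(v)])
    if (!length(v)) return(NA_real_)
    hpos <- (length(v) - 1) * p + 1
    lo <- floor(hpos); hi <- ceiling(hpos)
    v[lo] + (hpos - lo) * (v[hi] - v[lo])
  }
  for (k in unique(kb)) {
    inb <- kb == k
    row <- st2$perBin[k, ]
    expect_equal(row$median_ndvi,
                 sortQuartile(st2$perCity$mean_ndvi[inb], 0.5),
                 tolerance = 1e-12)
    expect_equal(row$q25_indicator,
                 sortQuartile(st2$perCity$indicator[inb], 0.25),
                 tolerance = 1e-12)
    expect_equal(row$q75_indicator,
                 sortQuartile(st2$perCity$indicator[inb], 0.75),
                 tolerance = 1e-12)
  }
})
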