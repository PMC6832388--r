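test_that("energy-to-water conversion uses the latent-heat constant", {
  # 1 J m^-2 per 12 h -> 2.920e-7 m/yr water equivalent
  expect_equal(energyToWaterEquivalent(1), 2.920e-7, tolerance = 1e-12)
  expect_identical(energyToWaterEquivalent(0), 0)
  # linear scaling
  expect_equal(energyToWaterEquivalent(1e7), 2.920, tolerance = 1e-12)
  expect_equal(energyToWaterEquivalent(c(2, 4)),
               2 * energyToWaterEquivalent(c(1, 2)), tolerance = 1e-15)
})

test_that("Schreiber's equation of state behaves as an evaporative fraction", {
  expect_identical(schreiberRatio(0), 0)
  expect_equal(schreiberRatio(1), 1 - exp(-1), tolerance = 1e-15)
  expect_equal(schreiberRatio(1), 0.6321206, tolerance = 1e-7)
  expect_lte(schreiberRatio(50), 1)  # asymptote (rounds to 1 in double)
  expect_gt(schreiberRatio(50), 1 - 1e-10)
  D <- seq(0, 10, by = 0.01)
  expect_true(all(diff(schreiberRatio(D)) > 0))
  expect_error(schreiberRatio(-0.1), ">= 0")
})

test_that("the precipitation isoline is Schreiber-consistent", {
  expect_identical(precipitationIsoline(0, 1), 0)
  # D = 1 identity: P = 1, E = 1 - 1/e gives H = 1/e (N = P)
  expect_equal(precipitationIsoline(1 - exp(-1), 1), exp(-1),
               tolerance = 1e-12)
  expect_error(precipitationIsoline(1, 1), "cannot reach")
  expect_error(precipitationIsoline(-0.1, 1), "non-negative")

  # round-trip: recomputing D = (E+H)/P and applying Schreiber returns E/P
  set.seed(3)
  P <- runif(200, 0.3, 3)
  E <- P * runif(200, 0.01, 0.99)
  H <- precipitationIsoline(E, P)
  D <- (E + H) / P
  expect_lt(max(abs(schreiberRatio(D) - E / P)), 1e-10)
})

test_that("the dryness isoline matches algebra and a root-solve oracle", {
  expect_equal(drynessIsoline(1, 1), (1 - exp(-1)) / exp(-1),
               tolerance = 1e-12)
  expect_equal(drynessIsoline(1, 1), 1.718282, tolerance = 1e-6)
  expect_identical(drynessIsoline(0, 2), 0)
  expect_error(drynessIsoline(1, 1e-9), "D too close to 0")
  expect_error(drynessIsoline(-1, 1), ">= 0")

  # independent oracle: solve the two balance equations numerically for E
  # given (H, D): find P with D = (E+H)/P and E/P = 1 - exp(-D)
  for (D in c(0.5, 1, 3)) {
    H <- 1
    f <- function(E) {
      P <- (E + H) / D
      E / P - (1 - exp(-D))
    }
    sol <- stats::uniroot(f, c(1e-9, 100), tol = 1e-14)$root
    expect_equal(drynessIsoline(H, D), sol, tolerance = 1e-8)
  }
})

test_that("dryness and precipitation isolines parameterize one surface", {
  # grid of (D, H) pairs round-trips to the starting D within 1e-8
  set.seed(12)
  D <- runif(500, 0.05, 6)
  H <- runif(500, 1e-3, 3)
  E <- drynessIsoline(H, D)
  P <- (E + H) / D
  H2 <- precipitationIsoline(E, P)
  D2 <- (E + H2) / P
  expect_lt(max(abs(D2 - D)), 1e-8)
})

test_that("dryness regimes split at the Budyko boundaries", {
  expect_identical(as.character(classifyDrynessRegime(0.2)), "tundra")
  expect_identical(as.character(classifyDrynessRegime(1.5)),
                   "steppe_savanna")
  expect_identical(as.character(classifyDrynessRegime(2.5)), "semi_desert")
  expect_identical(as.character(classifyDrynessRegime(5)), "desert")
  # boundaries belong to the drier (upper) class
  expect_identical(as.character(classifyDrynessRegime(1 / 3)), "forest")
  expect_identical(as.character(classifyDrynessRegime(1)), "steppe_savanna")
  expect_error(classifyDrynessRegime(-1), ">= 0")

  # evaporative fractions at the regime boundaries are the Schreiber
  # constants 1-e^(-1/3), 1-e^-1, 1-e^-2, 1-e^-3
  expect_equal(schreiberRatio(c(1 / 3, 1, 2, 3)),
               c(1 - exp(-1 / 3), 1 - exp(-1), 1 - exp(-2), 1 - exp(-3)),
               tolerance = 1e-15)
})

test_that("state-space embedding bins mass correctly", {
  g <- toyGrid(1)
  E1 <- GridRaster(matrix(0.55), g$latEdges, g$lonEdges)
  H1 <- GridRaster(matrix(1.25), g$latEdges, g$lonEdges)
  h <- embedStateSpace(E1, H1, eEdges = seq(0, 2, 0.5),
                       hEdges = seq(0, 2, 0.5))
  W <- histWeights(h)
  expect_equal(sum(W), 1)
  expect_equal(W[2, 3], 1)  # E in [0.5,1), H in [1,1.5)

  # uniform weights scale the mass, not the shape
  g8 <- toyGrid(8)
  set.seed(21)
  E <- GridRaster(matrix(runif(64, 0.05, 1.9), 8, 8), g8$latEdges,
                  g8$lonEdges)
  H <- GridRaster(matrix(runif(64, 0, 1.9), 8, 8), g8$latEdges,
                  g8$lonEdges)
  w3 <- GridRaster(matrix(3, 8, 8), g8$latEdges, g8$lonEdges)
  h1 <- embedStateSpace(E, H, eEdges = seq(0, 2, 0.25),
                        hEdges = seq(0, 2, 0.25))
  h3 <- embedStateSpace(E, H, w3, eEdges = seq(0, 2, 0.25),
                        hEdges = seq(0, 2, 0.25))
  expect_equal(histWeights(h3), 3 * histWeights(h1), tolerance = 1e-12)
})

test_that("embedding matches the brute-force binning oracle", {
  set.seed(33)
  n <- 500
  side <- ceiling(sqrt(n))
  g <- toyGrid(side)
  e <- runif(side^2, -0.2, 2.2)   # includes invalid E <= 0
  h <- runif(side^2, -0.2, 2.2)
  w <- rpois(side^2, 4)
  E <- GridRaster(matrix(e, side), g$latEdges, g$lonEdges)
  H <- GridRaster(matrix(h, side), g$latEdges, g$lonEdges)
  W <- GridRaster(matrix(w, side), g$latEdges, g$lonEdges)
  eE <- seq(0, 2, 0.4); eH <- seq(0, 2, 0.4)
  got <- histWeights(embedStateSpace(E, H, W, eEdges = eE, hEdges = eH))
  oracle <- bruteBin2d(e, h, w, eE, eH)
  # the oracle drops out-of-range pairs exactly like the implementation
  expect_equal(got, oracle, tolerance = 1e-12)

  # count weights: integer mass equal to the number of embedded pixels
  got1 <- embedStateSpace(E, H, eEdges = seq(-1, 3, 0.5),
                          hEdges = seq(-1, 3, 0.5))
  expect_equal(histMass(got1), sum(e > 0 & h >= 0))
})

test_that("Gaussian smoothing preserves mass and spreads variance", {
  set.seed(44)
  W <- matrix(0, 21, 21); W[11, 11] <- 5
  h0 <- new("StateSpaceHistogram", eEdges = 0:21 / 10, hEdges = 0:21 / 10,
            weights = W, bandwidth = 0, nExcluded = 0L)
  expect_identical(histWeights(smoothHistogram(h0, 0)), W)  # identity

  hs <- smoothHistogram(h0, 2)
  expect_equal(histMass(hs), 5, tolerance = 1e-9)
  expect_true(all(histWeights(hs) >= 0))

  # point mass at the center: marginal variance of the smoothed histogram
  # equals the kernel variance (bandwidth^2 in bin units)
  Wm <- histWeights(hs)
  marg <- rowSums(Wm) / sum(Wm)
  m <- sum(seq_len(21) * marg)
  v <- sum((seq_len(21) - m)^2 * marg)
  expect_equal(v, 4, tolerance = 0.05)

  # large bandwidth spreads a point mass almost uniformly, mass conserved
  hb <- smoothHistogram(h0, 50)
  expect_equal(histMass(hb), 5, tolerance = 1e-9)
  expect_lt(diff(range(histWeights(hb))), 0.02 * max(histWeights(hb)))
})
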