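test_that("generated predictor pairs hit their target correlation", {
  flat <- function(st, nm) {
    v <- gridValues(getLayer(st, nm)); v[gridMask(st)]
  }
  r0 <- makeStack(rows = 100, cols = 100, seed = 3, r = 0)
  expect_lt(abs(cor(flat(r0, "env1"), flat(r0, "env2"))), 0.15)

  r1 <- makeStack(rows = 50, cols = 50, seed = 3, r = 1)
  expect_gt(cor(flat(r1, "env1"), flat(r1, "env2")), 0.99)

  # convergence at larger grids, a middling target
  r6 <- makeStack(rows = 300, cols = 300, seed = 7, r = 0.6)
  expect_lt(abs(cor(flat(r6, "env1"), flat(r6, "env2")) - 0.6), 0.05)
})

test_that("indefinite target correlation matrices are rejected with a diagnostic", {
  C <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  cfg <- landscapeConfig(10, 10, nContinuous = 3, targetCorrelations = C,
                         seed = 1)
  expect_error(simulatePredictors(cfg), "positive semi-definite")
  expect_error(landscapeConfig(10, 10, nContinuous = 2,
                               targetCorrelations = matrix(c(1, 0.2, 0.4, 1), 2, 2)),
               "symmetric")
})

test_that("the categorical layer holds exactly the requested class IDs", {
  st <- makeStack(rows = 30, cols = 30, seed = 2, nClasses = 3)
  lc <- gridValues(getLayer(st, "landcover"))
  expect_setequal(unique(as.vector(lc)), c(1, 2, 3))
  expect_true(isCategorical(getLayer(st, "landcover")))
})

test_that("truth suitability is a normalised monotone exponential", {
  st <- makeContStack(rows = 10, cols = 10, seed = 4)
  # all-zero weights are rejected; near-zero gives the uniform limit
  expect_error(syntheticTruth("L", "env1", 0), "nonzero")
  flatTruth <- syntheticTruth("L", "env1", 1e-12)
  u <- truthSuitability(st, flatTruth)
  expect_equal(gridValues(u)[gridMask(u)], rep(1 / 100, 100), tolerance = 1e-9)

  tr <- syntheticTruth("L", "env1", 5)
  su <- truthSuitability(st, tr)
  v <- gridValues(su)[gridMask(su)]
  expect_equal(sum(v), 1, tolerance = 1e-9)
  ord <- order(gridValues(getLayer(st, "env1"))[gridMask(st)])
  expect_true(all(diff(v[ord]) > 0))     # strictly increasing in the layer

  expect_error(truthSuitability(st, syntheticTruth("L", "nope", 1)), "nope")
})

test_that("presence sampling is proportional, degenerate-safe and reproducible", {
  st <- makeContStack(rows = 10, cols = 10, seed = 4)
  u <- truthSuitability(st, syntheticTruth("L", "env1", 1e-12))  # uniform
  occ <- samplePresences(u, 10000, seed = 8)
  counts <- table(factor(cellFromXY(u, coords(occ)), levels = 1:100))
  expect_gt(chisq.test(as.vector(counts))$p.value, 0.001)

  # all mass in one cell
  vals <- matrix(0, 5, 5); vals[3, 3] <- 1
  onecell <- rasterGrid(vals)
  pts <- samplePresences(onecell, 50, seed = 1)
  expect_equal(nrow(unique(coords(pts))), 1)

  expect_identical(coords(samplePresences(u, 40, seed = 5)),
                   coords(samplePresences(u, 40, seed = 5)))
  expect_error(samplePresences(rasterGrid(matrix(0, 2, 2)), 5), "zero")
})

test_that("land-cover pairs follow the transition spec", {
  idSpec <- transitionSpec(diag(3), intervalYears = 10)
  pair <- simulateLandcoverPair(idSpec, rows = 40, cols = 40, seed = 3)
  expect_identical(gridValues(pair$t1), gridValues(pair$t2))

  P <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.8, 0.1,
                0.05, 0.05, 0.9), 3, 3, byrow = TRUE)
  sp <- transitionSpec(P, intervalYears = 10)
  pair <- simulateLandcoverPair(sp, rows = 300, cols = 300, seed = 11)
  emp <- crosstabTransition(pair$t1, pair$t2, intervalYears = 10)
  expect_lt(max(abs(emp@P - P)), 0.02)
  # cell count conserved
  expect_equal(sum(gridMask(pair$t2)), 300 * 300)

  expect_error(transitionSpec(matrix(c(0.5, 0.4, 0, 1), 2, 2, byrow = TRUE)),
               "sum to 1")
})

test_that("driver effects can forbid a transition where the driver is negative", {
  st <- makeContStack(rows = 50, cols = 50, seed = 9)
  P <- matrix(c(0.6, 0.4, 0.3, 0.7), 2, 2, byrow = TRUE)
  sp <- transitionSpec(P, intervalYears = 10,
                       driverEffects = list(list(from = 1, to = 2,
                                                 driver = "env1",
                                                 fun = function(d) as.numeric(d >= 0))))
  pair <- simulateLandcoverPair(sp, drivers = st, seed = 2)
  d <- gridValues(getLayer(st, "env1"))
  moved <- gridValues(pair$t1) == 1 & gridValues(pair$t2) == 2
  expect_true(all(d[moved] >= 0))
  expect_error(simulateLandcoverPair(sp, rows = 10, cols = 10, seed = 1),
               "driver")
})

test_that("generators are bit-reproducible under a fixed seed", {
  s1 <- makeStack(rows = 15, cols = 15, seed = 77)
  s2 <- makeStack(rows = 15, cols = 15, seed = 77)
  expect_identical(gridValues(getLayer(s1, "env1")),
                   gridValues(getLayer(s2, "env1")))
  sp <- transitionSpec(matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE))
  p1 <- simulateLandcoverPair(sp, rows = 20, cols = 20, seed = 5)
  p2 <- simulateLandcoverPair(sp, rows = 20, cols = 20, seed = 5)
  expect_identical(gridValues(p1$t2), gridValues(p2$t2))
})
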