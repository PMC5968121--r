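test_that("the ten-percentile threshold is the ceiling order statistic", {
  expect_equal(tenPercentileThreshold(seq(0.1, 1, by = 0.1)), 0.1)
  expect_equal(tenPercentileThreshold(rep(0.42, 7)), 0.42)
  set.seed(14)
  x <- runif(100)                         # distinct values
  tau <- tenPercentileThreshold(x)
  expect_equal(sum(x < tau), 9)           # exactly 9 strictly below
  expect_error(tenPercentileThreshold(numeric(0)), "no training")
})

test_that("binarisation is monotone in the threshold with exact edge cases", {
  st <- makeContStack(rows = 10, cols = 10, seed = 16)
  map <- truthSuitability(st, syntheticTruth("L", "env1", 3))
  v <- gridValues(map)[gridMask(map)]
  expect_equal(binarizeMap(map, max(v) * 1.01)@suitableCount, 0)
  expect_equal(binarizeMap(map, min(v))@suitableCount, 100)
  taus <- sort(sample(v, 10))
  counts <- vapply(taus, function(t) binarizeMap(map, t)@suitableCount,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("replicate runs partition occurrences and average their maps", {
  st <- makeContStack(rows = 15, cols = 15, seed = 18)
  su <- truthSuitability(st, makeTruth())
  occ <- cleanAndRarefy(samplePresences(su, 300, seed = 3), st)
  bg <- sampleBackground(st, 225, seed = 1)
  reps <- runReplicates(occ, bg, st, classes = c("L", "Q"),
                        regMultiplier = 1, n = 4, seed = 7)
  # each partition covers every occurrence exactly once
  for (p in reps@partitions) {
    expect_equal(sort(c(p$train, p$test)), seq_len(nOccurrences(occ)))
    expect_equal(length(p$train), floor(0.75 * nOccurrences(occ)))
  }
  # the mean map is the arithmetic mean of the replicate maps
  manual <- Reduce(`+`, lapply(reps@maps, gridValues)) / 4
  expect_equal(gridValues(reps@meanMap), manual, tolerance = 1e-12)
  # same seed, same everything
  reps2 <- runReplicates(occ, bg, st, classes = c("L", "Q"),
                         regMultiplier = 1, n = 4, seed = 7)
  expect_identical(gridValues(reps2@meanMap), gridValues(reps@meanMap))
})

test_that("a single full-data replicate equals the plain fitted map", {
  st <- makeContStack(rows = 12, cols = 12, seed = 19)
  su <- truthSuitability(st, makeTruth())
  occ <- cleanAndRarefy(samplePresences(su, 200, seed = 5), st)
  bg <- sampleBackground(st, 144, seed = 1)
  reps <- runReplicates(occ, bg, st, classes = c("L", "Q"),
                        regMultiplier = 1, n = 1, trainFrac = 1, seed = 2)
  bf <- expandFeatures(extractValues(st, bg), classes = c("L", "Q"))
  fit <- fitMaxent(expandFeatures(extractValues(st, occ), reference = bf), bf,
                   regMultiplier = 1)
  expect_equal(gridValues(reps@meanMap), gridValues(predictLogistic(fit, st)),
               tolerance = 1e-12)
  expect_true(is.na(reps@aucTest[1]))    # empty validation side
})

test_that("replicate test AUC is high when the truth is strongly informative", {
  st <- makeContStack(rows = 20, cols = 20, seed = 20)
  su <- truthSuitability(st, syntheticTruth(c("L", "L"), c("env1", "env2"),
                                            c(8, 5)))
  occ <- cleanAndRarefy(samplePresences(su, 200, seed = 6), st)
  bg <- sampleBackground(st, 400, seed = 1)
  reps <- runReplicates(occ, bg, st, classes = c("L", "Q"),
                        regMultiplier = 1, n = 5, seed = 9)
  expect_gt(mean(reps@aucTest), 0.8)
})

test_that("identity scenarios change nothing and toy deltas count exactly", {
  st <- makeContStack(rows = 12, cols = 12, seed = 22)
  su <- truthSuitability(st, makeTruth())
  occ <- cleanAndRarefy(samplePresences(su, 250, seed = 8), st)
  bg <- sampleBackground(st, 144, seed = 1)
  reps <- runReplicates(occ, bg, st, classes = c("L", "Q"),
                        regMultiplier = 1, n = 2, seed = 4)
  tau <- tenPercentileThreshold(
    gridValues(reps@meanMap)[cellFromXY(reps@meanMap, coords(occ))])
  current <- binarizeMap(reps@meanMap, tau)
  same <- projectScenario(reps, st, "identity", tau, current)
  expect_identical(same@percentChange, 0)
  expect_identical(gridValues(same@thresholded@binary),
                   gridValues(current@binary))

  # -40% from 100 -> 60 suitable cells, straight arithmetic
  expect_equal(areaChange(100, 60), -40)

  # a missing predictor is named
  broken <- rasterStack(st@layers["env1"])
  expect_error(projectScenario(reps, broken, "x", tau, current), "env2")
})

test_that("uniformly degrading a positively weighted predictor shrinks the range", {
  st <- makeContStack(rows = 15, cols = 15, seed = 23)
  su <- truthSuitability(st, syntheticTruth("L", "env1", 6))
  occ <- cleanAndRarefy(samplePresences(su, 400, seed = 2), st)
  bg <- sampleBackground(st, 225, seed = 1)
  reps <- runReplicates(occ, bg, st, classes = "L", regMultiplier = 0.5,
                        n = 2, seed = 3)
  tau <- tenPercentileThreshold(
    gridValues(reps@meanMap)[cellFromXY(reps@meanMap, coords(occ))])
  current <- binarizeMap(reps@meanMap, tau)
  shifted <- st@layers
  g <- shifted$env1
  g@values <- g@values - 2 * sd(gridValues(g)[gridMask(g)])
  shifted$env1 <- g
  worse <- projectScenario(reps, rasterStack(shifted), "cooler", tau, current)
  expect_lte(worse@percentChange, 0)
  expect_gte(worse@percentChange, -100)
})
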