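test_that("rank AUC counts outranking pairs with half-credit ties", {
  expect_equal(rankAUC(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(rankAUC(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(rankAUC(c(1, 2), c(1, 2)), 0.5)          # exchangeable
  expect_equal(rankAUC(c(1, 1), c(1, 1)), 0.5)          # pure ties
  expect_error(rankAUC(numeric(0), 1), "non-empty")
})

test_that("AUC is antisymmetric under argument swap", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(30); b <- rnorm(40, mean = runif(1, -1, 1))
    expect_equal(rankAUC(a, b), 1 - rankAUC(b, a), tolerance = 1e-12)
  }
})

test_that("AUC bands follow the conventional ranges with upper-boundary ties", {
  expect_equal(aucBand(0.75), "Fair")
  expect_equal(aucBand(0.9), "Excellent")
  expect_equal(aucBand(0.42), "worse than random")
  expect_equal(aucBand(0.5), "Failed")
  expect_equal(aucBand(0.6), "Poor")
  expect_equal(aucBand(0.8), "Good")
  expect_equal(aucBand(1), "Excellent")
})

test_that("Boyce index hits its bounds for perfect agreement and reversal", {
  land <- seq(0, 1, length.out = 101)
  # deterministic presences with multiplicity increasing in suitability:
  # every window's P/E is the window mean multiplicity, strictly monotone
  up <- boyceIndex(rep(land, times = 1:101), land, windowCount = 21)
  expect_equal(up$CBI, 1)
  down <- boyceIndex(rep(land, times = 101:1), land, windowCount = 21)
  expect_equal(down$CBI, -1)
  expect_true(all(up$PE >= 0))
})

test_that("Boyce index is invariant under strictly monotone transforms", {
  set.seed(12)
  land <- runif(3000)
  pres <- sample(land, 500, replace = TRUE, prob = land + 0.2)
  b1 <- boyceIndex(pres, land)$CBI
  # windows are equal-width in score space, so compare rank-preserving
  # transforms through the empirical quantile map
  b2 <- boyceIndex(stats::ecdf(land)(pres), stats::ecdf(land)(land))$CBI
  expect_equal(sign(b1), sign(b2))
  expect_lt(abs(b1 - b2), 0.15)
})

test_that("Boyce window bookkeeping drops empty windows and demands three", {
  expect_error(boyceIndex(c(0.5), rep(0.5, 10)), "zero range")
  land <- c(rep(0, 50), rep(1, 50))
  expect_error(boyceIndex(c(0, 1), land, windowCount = 5,
                          windowFraction = 0.05), "fewer than 3")
})

test_that("presences sampled from a known truth give a strongly positive CBI", {
  st <- makeContStack(rows = 40, cols = 40, seed = 31)
  su <- truthSuitability(st, syntheticTruth("L", "env1", 6))
  occ <- samplePresences(su, 5000, seed = 2)
  suit <- gridValues(su)[gridMask(su)]
  presSuit <- gridValues(su)[cellFromXY(su, coords(occ))]
  expect_gt(boyceIndex(presSuit, suit)$CBI, 0.9)
})

test_that("jackknife gains separate informative from noise variables", {
  st <- makeContStack(rows = 20, cols = 20, seed = 33)
  su <- truthSuitability(st, syntheticTruth("L", "env1", 6))  # env2 is noise
  occ <- samplePresences(su, 1500, seed = 3)
  bg <- sampleBackground(st, 400, seed = 1)
  pd <- extractValues(st, occ); bd <- extractValues(st, bg)
  jk <- jackknifeGains(pd, bd, classes = c("L", "Q"), regMultiplier = 0.5)
  tab <- jk$table
  full <- jk$fullGain
  # dropping pure noise barely hurts; the informative variable alone
  # carries nearly the full gain
  expect_gt(tab$gainWithout[tab$variable == "env2"], 0.9 * full)
  expect_gt(tab$gainAlone[tab$variable == "env1"], 0.9 * full)
  expect_lt(tab$gainWithout[tab$variable == "env1"], 0.5 * full)
  # nested-model ordering: no variable alone beats the full model
  expect_true(all(tab$gainAlone <= full + 1e-8))
  expect_error(jackknifeGains(pd[, 1, drop = FALSE], bd[, 1, drop = FALSE]),
               "two variables")
})

test_that("percent contributions are nonnegative and sum to one hundred", {
  st <- makeContStack(rows = 20, cols = 20, seed = 34)
  su <- truthSuitability(st, syntheticTruth("L", "env1", 6))
  inp <- fitInputs(st, su, nPres = 1000, presSeed = 4)
  fit <- fitMaxent(inp$pres, inp$bg, regMultiplier = 1)
  pc <- percentContribution(fit)
  expect_equal(sum(pc), 100, tolerance = 0.1)
  expect_true(all(pc >= 0))
  expect_gt(pc["env1"], 90)              # the only informative variable

  # single-variable model concentrates everything
  one <- expandFeatures(data.frame(v = runif(50)), classes = "L")
  onePres <- expandFeatures(data.frame(v = runif(30)^2), reference = one)
  expect_equal(unname(suppressWarnings(
    percentContribution(fitMaxent(onePres, one)))), 100)
})

test_that("a zero-gain model yields uniform contributions with a warning", {
  Mb <- matrix(runif(60), 30, 2)
  fit <- fitMaxent(bareFeatures(Mb), bareFeatures(Mb), regMultiplier = 5)
  expect_warning(pc <- percentContribution(fit), "uniform")
  expect_equal(unname(pc), c(50, 50))
})
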