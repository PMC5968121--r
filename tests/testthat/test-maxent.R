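test_that("no signal gives zero weights and a uniform raw distribution", {
  set.seed(1)
  Mb <- matrix(runif(200), 50, 4)
  Mp <- Mb[rep(1:50, 2), ]               # presence means == background means
  fit <- fitMaxent(bareFeatures(Mp), bareFeatures(Mb), regMultiplier = 1)
  expect_true(all(abs(lambdas(fit)) < 1e-6))
  expect_equal(predictRaw(fit, bareFeatures(Mb)), rep(1 / 50, 50),
               tolerance = 1e-9)
})

test_that("a one-feature fit matches a brute-force grid search of the objective", {
  # two-cell landscape, binary feature; presence mean 0.75 keeps the
  # optimum interior (lambda* = logit(0.75))
  Mb <- matrix(c(0, 1), 2, 1)
  Mp <- matrix(c(1, 1, 1, 0), 4, 1)
  fit <- fitMaxent(bareFeatures(Mp), bareFeatures(Mb), regMultiplier = 0,
                   config = fitConfig(tolerance = 1e-12))
  grid <- seq(-5, 5, by = 1e-4)
  objs <- 0.75 * grid - vapply(grid, function(l) lse(c(0, l)), numeric(1))
  expect_equal(unname(lambdas(fit)), grid[which.max(objs)], tolerance = 1e-4)
  expect_equal(unname(lambdas(fit)), qlogis(0.75), tolerance = 1e-5)
})

test_that("fitting recovers a known L+Q truth on a synthetic landscape", {
  st <- makeContStack(rows = 20, cols = 20, seed = 42)
  tr <- makeTruth()
  su <- truthSuitability(st, tr)
  inp <- fitInputs(st, su, nPres = 2000, presSeed = 1)
  fit <- fitMaxent(inp$pres, inp$bg, regMultiplier = 0.001,
                   config = fitConfig(tolerance = 1e-8))
  lam <- lambdas(fit)
  truthLam <- setNames(numeric(length(lam)), names(lam))
  truthLam[c("L(env1)", "Q(env1)", "L(env2)")] <- c(6, -4, 3)
  relL2 <- sqrt(sum((lam - truthLam)^2) / sum(truthLam^2))
  expect_lt(relL2, 0.35)                 # single-draw sampling noise bound
  expect_gt(lam["L(env1)"], 0)
  expect_lt(lam["Q(env1)"], 0)
})

test_that("raw prediction is normalised over the background and monotone in lambda", {
  set.seed(3)
  Mb <- matrix(runif(40), 10, 4)
  Mp <- Mb[sample(10, 20, replace = TRUE, prob = (1:10)^2), ]
  bf <- bareFeatures(Mb); pf <- bareFeatures(Mp)
  fit <- fitMaxent(pf, bf, regMultiplier = 0.5)
  expect_equal(sum(predictRaw(fit, bf)), 1, tolerance = 1e-9)

  # doubling a positive weight raises the relative probability of the
  # cell maximising that feature (brute-force recomputation)
  lam <- lambdas(fit)
  j <- which(lam > 0)[1]
  skip_if(is.na(j))
  top <- which.max(Mb[, j])
  rel1 <- predictRaw(fit, bf) / max(predictRaw(fit, bf))
  lam2 <- lam; lam2[j] <- 2 * lam2[j]
  s <- as.vector(Mb %*% lam2)
  q2 <- exp(s - lse(s))
  expect_gt(q2[top] / sum(q2), predictRaw(fit, bf)[top])
})

test_that("logistic output anchors typical sites at one half", {
  # uniform over 4 cells: H = log 4, q = 1/4 -> logistic exactly 0.5
  Mb <- matrix(c(0, 0, 0, 0), 4, 1)
  Mp <- matrix(0, 2, 1)
  fit <- fitMaxent(bareFeatures(Mp), bareFeatures(Mb))
  expect_equal(entropy(fit), log(4))
  expect_equal(predictLogistic(fit, bareFeatures(Mb)), rep(0.5, 4))

  # monotone in q, limits at 0
  set.seed(4)
  Mb <- matrix(runif(30), 30, 1)
  Mp <- Mb[sample(30, 50, replace = TRUE, prob = Mb[, 1] + 0.1), , drop = FALSE]
  fit <- fitMaxent(bareFeatures(Mp), bareFeatures(Mb), regMultiplier = 0.1)
  q <- predictRaw(fit, bareFeatures(Mb))
  l <- predictLogistic(fit, bareFeatures(Mb))
  expect_true(all(diff(l[order(q)]) >= 0))
  expect_true(all(l > 0 & l < 1))
  # a cell whose raw probability equals exp(-H) scores exactly 0.5
  qStar <- exp(-entropy(fit))
  expect_equal(plogis(entropy(fit) + log(qStar)), 0.5)
})

test_that("response curves are flat without dependence, monotone with it", {
  st <- makeContStack(rows = 15, cols = 15, seed = 6)
  su <- truthSuitability(st, syntheticTruth("L", "env1", 4))
  inp <- fitInputs(st, su, nPres = 800, presSeed = 2, classes = "L")
  fit <- fitMaxent(inp$pres, inp$bg, regMultiplier = 0.1)
  rc <- responseCurve(fit, "env1", n = 30)
  expect_true(all(diff(rc$suitability) > 0))
  expect_error(responseCurve(fit, "nothere"), "unknown variable")

  # all-zero model: flat curve
  Mb <- matrix(runif(20), 20, 1)
  flatFit <- fitMaxent(bareFeatures(Mb), bareFeatures(Mb), regMultiplier = 1)
  expect_true(all(abs(lambdas(flatFit)) < 1e-8))
})

test_that("regularised gain never decreases along the trajectory", {
  st <- makeContStack(rows = 15, cols = 15, seed = 8)
  su <- truthSuitability(st, makeTruth())
  for (reg in c(0, 0.5, 2)) {
    inp <- fitInputs(st, su, nPres = 300, presSeed = reg * 10 + 3)
    fit <- fitMaxent(inp$pres, inp$bg, regMultiplier = reg)
    expect_true(all(diff(fit@gainTrajectory) >= -1e-12))
  }
})

test_that("stronger regularisation never yields a denser model", {
  st <- makeContStack(rows = 15, cols = 15, seed = 10)
  su <- truthSuitability(st, makeTruth())
  inp <- fitInputs(st, su, nPres = 400, presSeed = 5,
                   classes = c("L", "Q", "H"), knots = 5)
  sizes <- vapply(c(0.1, 1, 3, 6, 10), function(b)
    sum(lambdas(fitMaxent(inp$pres, inp$bg, regMultiplier = b)) != 0),
    numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("at zero penalty the fitted distribution matches presence feature means", {
  set.seed(11)
  Mb <- matrix(runif(120), 40, 3)
  Mp <- Mb[sample(40, 300, replace = TRUE, prob = runif(40)), ]
  bf <- bareFeatures(Mb); pf <- bareFeatures(Mp)
  fit <- fitMaxent(pf, bf, regMultiplier = 0,
                   config = fitConfig(tolerance = 1e-12, maxIter = 50000))
  q <- predictRaw(fit, bf)
  expect_equal(as.vector(crossprod(Mb, q)), unname(colMeans(Mp)),
               tolerance = 1e-4)
})

test_that("non-finite features and mismatched definitions are rejected", {
  Mb <- matrix(c(0, 1, NA, 1), 2, 2)
  expect_error(bareFeatures(Mb), "finite")
  a <- bareFeatures(matrix(runif(10), 5, 2))
  b <- bareFeatures(matrix(runif(15), 5, 3))
  expect_error(fitMaxent(a, b), "different feature definitions")
  fit <- fitMaxent(a, a)
  expect_error(predictRaw(fit, b), "different feature definitions")
})
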