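test_that("cross-tabulation counts transitions row-stochastically", {
  t1 <- toyGrid(matrix(c(1, 1, 2, 2), 1, 4), categorical = TRUE)
  t2 <- toyGrid(matrix(c(1, 2, 2, 2), 1, 4), categorical = TRUE)
  tm <- crosstabTransition(t1, t2)
  expect_equal(tm@P, matrix(c(0.5, 0, 0.5, 1), 2, 2,
                            dimnames = list(1:2, 1:2)))
  expect_equal(rowSums(tm@P), c("1" = 1, "2" = 1))

  # identical maps give the identity matrix
  id <- crosstabTransition(t1, t1)
  expect_equal(unname(id@P), diag(2))

  # classes absent at t1 get identity rows
  t3 <- toyGrid(matrix(c(1, 1, 1, 3), 1, 4), categorical = TRUE)
  tm3 <- crosstabTransition(t1, t3, classes = 1:3)
  expect_equal(unname(tm3@P[3, ]), c(0, 0, 1))

  off <- rasterGrid(matrix(1, 2, 2), origin = c(5, 5), categorical = TRUE)
  expect_error(crosstabTransition(t1, off), "aligned")
})

test_that("matrix powers follow the eigendecomposition closed form", {
  # identity is a fixed point at any horizon
  id <- transitionMatrix(diag(3), intervalYears = 10)
  expect_equal(scaleTransition(id, 35)@P, diag(3), ignore_attr = TRUE)

  P <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)
  tm <- transitionMatrix(P, intervalYears = 10)
  # unit power returns the input
  expect_equal(scaleTransition(tm, 10)@P, tm@P, tolerance = 1e-9,
               ignore_attr = TRUE)
  # closed form of this triangular chain: P^t = [[0.9^t, 1-0.9^t], [0, 1]]
  got <- scaleTransition(tm, 35)@P   # exponent 3.5
  expect_equal(unname(got),
               matrix(c(0.9^3.5, 1 - 0.9^3.5, 0, 1), 2, 2, byrow = TRUE),
               tolerance = 1e-6)
  # rows stay stochastic
  expect_equal(unname(rowSums(got)), c(1, 1), tolerance = 1e-9)
})

test_that("integer demand conserves per-class totals by largest remainder", {
  map <- toyGrid(matrix(c(rep(1, 7), rep(2, 3)), 1, 10), categorical = TRUE)
  tm <- transitionMatrix(matrix(c(0.55, 0.45, 0.2, 0.8), 2, 2, byrow = TRUE))
  D <- transitionDemand(tm, map)
  expect_equal(rowSums(D), c("1" = 7, "2" = 3))
  expect_equal(D["1", "2"], 3)   # 7 * 0.45 = 3.15 -> floor 3, remainder small
  expect_equal(D["1", "1"], 4)
})

test_that("allocation converts exactly the demanded highest-potential cells", {
  vals <- matrix(1, 10, 10); vals[, 6:10] <- 2
  map <- toyGrid(vals, categorical = TRUE)
  pot <- matrix(0, 10, 10); pot[, 1:5] <- matrix(seq(0.01, 0.5, length.out = 50), 10, 5)
  pots <- new("TransitionPotentialSet",
              pairs = data.frame(from = 1, to = 2),
              potentials = list("1->2" = toyGrid(pot)),
              arch = list())
  D <- matrix(0L, 2, 2, dimnames = list(1:2, 1:2)); diag(D) <- c(45L, 50L)
  D["1", "2"] <- 5L
  out <- allocateChange(map, D, pots, seed = 1)
  moved <- which(gridValues(map) == 1 & gridValues(out) == 2)
  expect_equal(sort(moved), sort(order(-as.vector(pot))[1:5]))  # top-5 ranking oracle
  # conservation and exact demanded counts
  expect_equal(sum(gridValues(out) == 1) + sum(gridValues(out) == 2), 100)
  ct <- crosstabTransition(map, out)
  expect_equal(ct@P["1", "2"] * 50, 5)

  # identity demand is a no-op
  D0 <- matrix(0L, 2, 2, dimnames = list(1:2, 1:2)); diag(D0) <- c(50L, 50L)
  expect_identical(gridValues(allocateChange(map, D0, pots, seed = 1)),
                   gridValues(map))
})

test_that("over-demand is scaled down with a warning, never inventing cells", {
  map <- toyGrid(matrix(c(1, 1, 2, 2), 2, 2), categorical = TRUE)
  D <- matrix(c(0L, 0L, 5L, 2L), 2, 2, dimnames = list(1:2, 1:2))
  expect_warning(out <- allocateChange(map, D, seed = 1), "exceeds")
  expect_equal(sum(gridValues(out) %in% 1:2), 4)
})

test_that("MLP potentials rank a perfectly separating driver correctly", {
  set.seed(5)
  n <- 30
  drv <- rasterGrid(matrix(rnorm(n * n), n, n))
  drivers <- rasterStack(d1 = drv)
  v1 <- matrix(1, n, n)
  # class 1 cells transition to 2 exactly where the driver is positive
  v2 <- ifelse(gridValues(drv) > 0, 2, 1)
  t1 <- toyGrid(v1, categorical = TRUE); t2 <- toyGrid(v2, categorical = TRUE)
  pots <- trainTransitionMLP(t1, t2, drivers, hiddenSize = 4, maxit = 200,
                             seed = 3)
  p <- gridValues(pots@potentials[["1->2"]])
  moved <- gridValues(t2) == 2
  expect_gt(rankAUC(p[moved], p[!moved]), 0.95)
})

test_that("MLP potentials are reproducible and flat under noise drivers", {
  set.seed(6)
  n <- 25
  drivers <- rasterStack(d1 = rasterGrid(matrix(rnorm(n * n), n, n)))
  t1 <- toyGrid(matrix(1, n, n), categorical = TRUE)
  t2 <- toyGrid(matrix(sample(1:2, n * n, TRUE), n, n), categorical = TRUE)
  a <- trainTransitionMLP(t1, t2, drivers, hiddenSize = 3, maxit = 100, seed = 9)
  b <- trainTransitionMLP(t1, t2, drivers, hiddenSize = 3, maxit = 100, seed = 9)
  expect_identical(gridValues(a@potentials[["1->2"]]),
                   gridValues(b@potentials[["1->2"]]))
  # uninformative driver: potential close to the base rate everywhere
  expect_lt(sd(gridValues(a@potentials[["1->2"]])), 0.1)

  # a source class with no observed change is skipped with a warning
  t2b <- toyGrid(matrix(1, n, n), categorical = TRUE)
  expect_warning(none <- trainTransitionMLP(t1, t2b, drivers, seed = 1), NA)
  expect_equal(length(none@potentials), 0)
})

test_that("class-area change recomputes percentages from areas", {
  t1 <- toyGrid(matrix(c(1, 1, 1, 2), 2, 2), cellSize = 2, categorical = TRUE)
  t2 <- toyGrid(matrix(c(1, 2, 2, 2), 2, 2), cellSize = 2, categorical = TRUE)
  tab <- classAreaChange(t1, t2)
  expect_equal(tab$areaT1, c(12, 4))     # cellArea = 4
  expect_equal(tab$percentChange, c(100 * (4 - 12) / 12, 100 * (12 - 4) / 4))
  expect_equal(areaChange(19.61, 12.53), -36.1, tolerance = 0.05)
})
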