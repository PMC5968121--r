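#' @include AllClasses.R
NULL

#' Configuration for a synthetic landscape
#'
#' Describes the synthetic predictor stack the generator emulates: a set
#' of spatially autocorrelated continuous layers with controllable
#' pairwise correlation, plus one categorical land-cover layer of patchy
#' classes. The defaults give a landscape a field ecologist would call
#' plausible at ~1 km resolution: smooth climatic-style gradients
#' (Gaussian smoothing over `smoothing` cells) and a handful of cover
#' classes in contiguous patches.
#'
#' @param rows,cols grid shape.
#' @param cellSize cell edge length (abstract planar units).
#' @param nContinuous number of continuous predictor layers.
#' @param targetCorrelations symmetric matrix in [-1, 1] (unit diagonal)
#'   of desired pairwise correlations between the continuous layers;
#'   defaults to the identity (uncorrelated). Must be positive
#'   semi-definite.
#' @param nLandcoverClasses number of land-cover classes (>= 2).
#' @param smoothing Gaussian smoothing radius in cells controlling spatial
#'   autocorrelation (standard deviation of the kernel).
#' @param seed integer seed.
#' @return a validated list of class `landscapeConfig`.
#' @export
landscapeConfig <- function(rows, cols, cellSize = 1, nContinuous = 3,
                            targetCorrelations = NULL,
                            nLandcoverClasses = 4, smoothing = 5,
                            seed = 1) {
  if (is.null(targetCorrelations)) targetCorrelations <- diag(nContinuous)
  targetCorrelations <- as.matrix(targetCorrelations)
  stopifnot(rows >= 1, cols >= 1, cellSize > 0, nContinuous >= 1,
            nLandcoverClasses >= 2, smoothing > 0)
  if (nrow(targetCorrelations) != nContinuous ||
      ncol(targetCorrelations) != nContinuous)
    stop("targetCorrelations must be nContinuous x nContinuous")
  if (max(abs(targetCorrelations - t(targetCorrelations))) > 1e-9)
    stop("targetCorrelations must be symmetric")
  if (max(abs(diag(targetCorrelations) - 1)) > 1e-9)
    stop("targetCorrelations must have unit diagonal")
  if (any(abs(targetCorrelations) > 1 + 1e-9))
    stop("targetCorrelations entries must lie in [-1, 1]")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cellSize = cellSize, nContinuous = as.integer(nContinuous),
                 targetCorrelations = targetCorrelations,
                 nLandcoverClasses = as.integer(nLandcoverClasses),
                 smoothing = smoothing, seed = as.integer(seed)),
            class = "landscapeConfig")
}

# Smoothed standard-normal random field: white noise convolved with a
# separable Gaussian kernel (padded so edges are unbiased), standardised.
.randomField <- function(rows, cols, smoothing) {
  half <- max(1L, as.integer(ceiling(3 * smoothing)))
  k <- stats::dnorm(seq(-half, half), sd = smoothing)
  k <- k / sum(k)
  z <- matrix(stats::rnorm((rows + 2 * half) * (cols + 2 * half)),
              rows + 2 * half, cols + 2 * half)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z <- z[(half + 1):(half + rows), (half + 1):(half + cols), drop = FALSE]
  as.vector(scale(as.vector(z)))
}

#' Generate a synthetic predictor stack
#'
#' Builds `nContinuous` spatially smooth standard-normal layers whose
#' empirical pairwise correlations match `targetCorrelations` (smoothed
#' white-noise fields are empirically whitened and then mixed through the
#' symmetric square root of the target matrix, so the sample correlation
#' is hit essentially exactly), plus one categorical land-cover layer cut
#' from an independent smooth field into `nLandcoverClasses`
#' quantile-balanced patchy classes with IDs `1..n`.
#'
#' @param config a [landscapeConfig()].
#' @return a [RasterStack-class] with layers `env1..envN` and `landcover`.
#' @export
simulatePredictors <- function(config) {
  stopifnot(inherits(config, "landscapeConfig"))
  C <- config$targetCorrelations
  ev <- eigen(C, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop(sprintf("targetCorrelations is not positive semi-definite (min eigenvalue %.3g)",
                 min(ev$values)))
  lam <- pmax(ev$values, 0)
  Csqrt <- ev$vectors %*% (sqrt(lam) * t(ev$vectors))
  n <- config$nContinuous
  .withSeed(config$seed, {
    Z <- vapply(seq_len(n),
                function(i) .randomField(config$rows, config$cols, config$smoothing),
                numeric(config$rows * config$cols))
    if (n > 1 && config$rows * config$cols > n) {
      # empirical whitening so the mixed fields carry the target correlation
      W <- chol(stats::cov(Z))
      Z <- Z %*% backsolve(W, diag(n))
    }
    X <- Z %*% Csqrt
    lc <- .randomField(config$rows, config$cols, config$smoothing)
    layers <- lapply(seq_len(n), function(i)
      rasterGrid(matrix(X[, i], config$rows, config$cols),
                 cellSize = config$cellSize))
    names(layers) <- paste0("env", seq_len(n))
    br <- stats::quantile(lc, probs = seq(0, 1, length.out = config$nLandcoverClasses + 1))
    br[1] <- -Inf; br[length(br)] <- Inf
    cls <- as.numeric(cut(lc, breaks = br, labels = FALSE))
    layers$landcover <- rasterGrid(matrix(cls, config$rows, config$cols),
                                   cellSize = config$cellSize,
                                   categorical = TRUE)
    rasterStack(layers)
  })
}

#' Define a known log-linear suitability truth
#'
#' A generating analogue of a fitted maximum-entropy model: feature
#' definitions over named layers with known weights `lambda*`, used to
#' build landscapes where the true habitat suitability is known exactly.
#'
#' @param kind feature kinds, each one of "L", "Q", "P", "T", "H", "C".
#' @param var,var2 source layer name(s); `var2` only for "P".
#' @param knot knot location (raw variable units) for "T"/"H".
#' @param level class level for "C".
#' @param weight true weights; at least one must be nonzero.
#' @return a data.frame of class `syntheticTruth`.
#' @export
syntheticTruth <- function(kind, var, weight, var2 = NA, knot = NA,
                           level = NA) {
  df <- data.frame(kind = kind, var = var, var2 = var2, knot = knot,
                   level = level, weight = weight,
                   stringsAsFactors = FALSE)
  stopifnot(all(df$kind %in% c("L", "Q", "P", "T", "H", "C")))
  if (all(df$weight == 0)) stop("truth needs at least one nonzero weight")
  class(df) <- c("syntheticTruth", "data.frame")
  df
}

#' True suitability surface of a synthetic truth
#'
#' Per-cell `exp(lambda* . f(x))`, normalised to sum to 1 over unmasked
#' cells. Features are computed like model features: min-max scaled on the
#' stack's own unmasked support.
#'
#' @param stack a [RasterStack-class].
#' @param truth a [syntheticTruth()].
#' @return a continuous [RasterGrid-class] summing to 1 over unmasked cells.
#' @export
truthSuitability <- function(stack, truth) {
  stopifnot(inherits(truth, "syntheticTruth"))
  vars <- unique(stats::na.omit(c(truth$var, truth$var2)))
  missing <- setdiff(vars, layerNames(stack))
  if (length(missing))
    stop(sprintf("truth references missing layer(s): %s",
                 paste(missing, collapse = ", ")))
  df <- cellTable(stack)
  eta <- numeric(nrow(df))
  rng <- lapply(df, range)
  sc <- function(v) {
    lo <- rng[[v]][1]; hi <- rng[[v]][2]
    if (hi == lo) return(rep(0, nrow(df)))
    (df[[v]] - lo) / (hi - lo)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    f <- switch(tr$kind,
      L = sc(tr$var),
      Q = sc(tr$var)^2,
      P = sc(tr$var) * sc(tr$var2),
      T = as.numeric(df[[tr$var]] > tr$knot),
      H = {
        hi <- rng[[tr$var]][2]
        if (hi <= tr$knot) rep(0, nrow(df)) else
          pmax(0, df[[tr$var]] - tr$knot) / (hi - tr$knot)
      },
      C = as.numeric(df[[tr$var]] == tr$level))
    eta <- eta + tr$weight * f
  }
  w <- exp(eta - .logSumExp(eta))
  mask <- gridMask(stack)
  vals <- matrix(NA_real_, nrow(mask), ncol(mask))
  vals[attr(df, "cell")] <- w
  rasterGrid(vals, mask = mask, origin = gridOrigin(stack),
             cellSize = cellSize(stack))
}

#' Sample presence points from a suitability surface
#'
#' Draws `n` cell-centre coordinates with replacement, with probability
#' proportional to the per-cell suitability — the sampling model under
#' which presence-only records reflect habitat quality exactly.
#'
#' @param suitability a [RasterGrid-class] of nonnegative weights.
#' @param n number of presences.
#' @param seed integer seed.
#' @return an [OccurrenceSet-class] of cell centres.
#' @export
samplePresences <- function(suitability, n, seed = NULL) {
  stopifnot(n >= 1)
  ctr <- cellCenters(suitability)
  p <- suitability@values[attr(ctr, "cell")]
  if (any(!is.finite(p)) || any(p < 0)) stop("suitability must be finite and >= 0")
  if (sum(p) <= 0) stop("suitability is zero everywhere; cannot sample presences")
  pick <- .withSeed(seed, sample.int(nrow(ctr), n, replace = TRUE, prob = p))
  occurrenceSet(ctr[pick, , drop = FALSE],
                provenance = sprintf("%d presences sampled from truth", n))
}

#' Specify a synthetic land-cover transition process
#'
#' A row-stochastic class transition matrix over a stated interval,
#' optionally modulated by driver variables: each `driverEffects` entry
#' multiplies the odds of one specific transition by `exp(coef * driver)`
#' (or by an arbitrary nonnegative `fun(driver)`), cell by cell, before
#' row renormalisation.
#'
#' @param P row-stochastic matrix.
#' @param classes integer class IDs.
#' @param intervalYears interval covered by one application of `P`.
#' @param driverEffects list of lists with elements `from`, `to`,
#'   `driver` (layer name), and `coef` or `fun`.
#' @return a list of class `transitionSpec`.
#' @export
transitionSpec <- function(P, classes = NULL, intervalYears = 10,
                           driverEffects = list()) {
  tm <- transitionMatrix(P, classes, intervalYears)  # validates stochasticity
  structure(list(matrix = tm, driverEffects = driverEffects),
            class = "transitionSpec")
}

#' Simulate a pair of land-cover maps with known transition truth
#'
#' The first map draws each cell's class independently from `prior`
#' (uniform by default); the second applies the spec's transition matrix
#' rows cell-by-cell, re-weighted by any driver effects and renormalised.
#' With no driver effects, the empirical cross-tabulation of the pair
#' converges to the spec's matrix as the grid grows.
#'
#' @param spec a [transitionSpec()].
#' @param rows,cols grid shape (ignored when `drivers` is given).
#' @param drivers optional [RasterStack-class] of driver layers referenced
#'   by the spec's effects; also supplies the grid geometry.
#' @param prior class prior for the first map (defaults to uniform).
#' @param seed integer seed.
#' @return list with categorical [RasterGrid-class] elements `t1`, `t2`.
#' @export
simulateLandcoverPair <- function(spec, rows = NULL, cols = NULL,
                                  drivers = NULL, prior = NULL, seed = NULL) {
  stopifnot(inherits(spec, "transitionSpec"))
  tm <- spec$matrix
  k <- length(tm@classes)
  if (!is.null(drivers)) {
    rows <- dim(drivers)[1]; cols <- dim(drivers)[2]
  }
  if (is.null(rows) || is.null(cols))
    stop("grid shape needed: give rows/cols or a drivers stack")
  if (is.null(prior)) prior <- rep(1 / k, k)
  stopifnot(length(prior) == k, all(prior >= 0), sum(prior) > 0)
  ncell <- rows * cols
  for (eff in spec$driverEffects) {
    if (is.null(drivers) || !eff$driver %in% layerNames(drivers))
      stop(sprintf("driver layer '%s' required by the spec is missing",
                   eff$driver))
  }
  .withSeed(seed, {
    t1 <- sample.int(k, ncell, replace = TRUE, prob = prior)
    W <- tm@P[t1, , drop = FALSE]         # per-cell transition rows
    for (eff in spec$driverEffects) {
      d <- as.vector(getLayer(drivers, eff$driver)@values)
      mult <- if (!is.null(eff$fun)) eff$fun(d) else exp(eff$coef * d)
      i <- match(eff$from, tm@classes); j <- match(eff$to, tm@classes)
      rows_i <- t1 == i
      W[rows_i, j] <- W[rows_i, j] * mult[rows_i]
    }
    W <- W / rowSums(W)
    u <- stats::runif(ncell)
    cum <- t(apply(W, 1, cumsum))
    t2 <- rowSums(u > cum) + 1L
    cs <- if (!is.null(drivers)) cellSize(drivers) else 1
    org <- if (!is.null(drivers)) gridOrigin(drivers) else c(0, 0)
    list(t1 = rasterGrid(matrix(tm@classes[t1], rows, cols), cellSize = cs,
                         origin = org, categorical = TRUE),
         t2 = rasterGrid(matrix(tm@classes[t2], rows, cols), cellSize = cs,
                         origin = org, categorical = TRUE))
  })
}
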