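#' @include AllClasses.R
NULL

#' Cross-tabulated land-cover transition matrix
#'
#' Estimates the class transition probabilities between two aligned
#' categorical maps: `P[i, j]` = (cells of class i at t1 and class j at
#' t2) / (cells of class i at t1). Classes absent at t1 receive identity
#' rows (they persist by assumption).
#'
#' @param mapT1,mapT2 aligned categorical [RasterGrid-class] maps.
#' @param intervalYears years separating the two maps.
#' @param classes optional class universe; defaults to the classes
#'   observed in either map.
#' @return a [TransitionMatrix-class].
#' @export
crosstabTransition <- function(mapT1, mapT2, intervalYears = 10,
                               classes = NULL) {
  if (!all(dim(mapT1) == dim(mapT2)) ||
      any(abs(gridOrigin(mapT1) - gridOrigin(mapT2)) > 1e-9) ||
      abs(cellSize(mapT1) - cellSize(mapT2)) > 1e-12)
    stop("maps are not aligned")
  if (!isCategorical(mapT1) || !isCategorical(mapT2))
    stop("both maps must be categorical")
  ok <- gridMask(mapT1) & gridMask(mapT2)
  v1 <- mapT1@values[ok]; v2 <- mapT2@values[ok]
  if (is.null(classes)) classes <- sort(unique(c(v1, v2)))
  k <- length(classes)
  tab <- table(factor(v1, levels = classes), factor(v2, levels = classes))
  P <- matrix(as.numeric(tab), k, k)
  rs <- rowSums(P)
  for (i in seq_len(k)) {
    if (rs[i] > 0) P[i, ] <- P[i, ] / rs[i]
    else { P[i, ] <- 0; P[i, i] <- 1 }   # absent class: identity row
  }
  transitionMatrix(P, classes = classes, intervalYears = intervalYears)
}

#' Rescale a transition matrix to a different horizon
#'
#' Raises the per-interval matrix to the real power
#' `targetYears / intervalYears` by eigendecomposition (the stationarity
#' assumption: per-interval transition behaviour is constant, so the
#' horizon matrix is a matrix power). Tiny negative entries produced by
#' the decomposition (< 1e-8 in magnitude) are clipped to zero and rows
#' renormalised. If the matrix is numerically non-diagonalisable or the
#' complex parts are material, the function falls back to repeated
#' multiplication with linear interpolation of the fractional step and
#' flags the result with attribute `method = "interpolated"`.
#'
#' @param m a [TransitionMatrix-class].
#' @param targetYears projection horizon in years (> 0).
#' @return a [TransitionMatrix-class] over `targetYears`.
#' @export
scaleTransition <- function(m, targetYears) {
  stopifnot(is(m, "TransitionMatrix"), targetYears > 0)
  e <- targetYears / m@intervalYears
  P <- m@P
  k <- nrow(P)
  method <- "eigen"
  Pe <- tryCatch({
    ed <- eigen(P)
    V <- ed$vectors
    if (abs(det(V)) < 1e-12) stop("non-diagonalisable")
    A <- V %*% diag(as.complex(ed$values)^e, k) %*% solve(V)
    if (max(abs(Im(A))) > 1e-8) stop("material complex part")
    Re(A)
  }, error = function(err) {
    method <<- "interpolated"
    whole <- floor(e); frac <- e - whole
    A <- diag(k)
    if (whole > 0) for (i in seq_len(whole)) A <- A %*% P
    if (frac > 0) A <- A %*% ((1 - frac) * diag(k) + frac * P)
    A
  })
  if (min(Pe) < -1e-8)
    warning(sprintf("matrix power produced negative entries down to %.3g; clipped",
                    min(Pe)))
  Pe[Pe < 0] <- 0
  Pe <- Pe / rowSums(Pe)
  out <- transitionMatrix(Pe, classes = m@classes, intervalYears = targetYears)
  attr(out, "method") <- method
  out
}

#' Train MLP transition-potential models
#'
#' For each source class with at least two observed destination classes,
#' trains one feed-forward network (single hidden layer of logistic
#' units, softmax outputs — via [nnet::nnet()]) on a balanced, seeded
#' sample of transitioned and persistent cells, predicting the
#' destination class from the driver variables. The per-cell predicted
#' probability of each observed transition `i -> j` (i != j) becomes that
#' transition's potential surface. Transitions never observed between
#' the two maps are not modelled; a source class whose cells all persist
#' is skipped with a warning.
#'
#' @param mapT1,mapT2 aligned categorical maps.
#' @param drivers [RasterStack-class] of driver variables.
#' @param hiddenSize hidden-layer width (default 10).
#' @param maxit optimiser iteration cap (default 1000).
#' @param maxPerClass cap on training cells sampled per destination class.
#' @param seed integer seed (network initialisation + sampling).
#' @return a [TransitionPotentialSet-class].
#' @export
trainTransitionMLP <- function(mapT1, mapT2, drivers, hiddenSize = 10,
                               maxit = 1000, maxPerClass = 1000,
                               seed = NULL) {
  stopifnot(is(drivers, "RasterStack"))
  ok <- gridMask(mapT1) & gridMask(mapT2) & gridMask(drivers)
  v1 <- mapT1@values[ok]; v2 <- mapT2@values[ok]
  X <- as.matrix(as.data.frame(lapply(drivers@layers,
                                      function(l) l@values[ok])))
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  pairs <- list(); pots <- list()
  .withSeed(seed, {
    for (i in sort(unique(v1))) {
      rows <- which(v1 == i)
      dests <- sort(unique(v2[rows]))
      if (length(dests) < 2) {
        if (!identical(dests, i))
          warning(sprintf("source class %g has a single destination; skipped", i))
        next
      }
      # balanced sample across destination classes
      pick <- unlist(lapply(dests, function(j) {
        r <- rows[v2[rows] == j]
        if (length(r) > maxPerClass) sample(r, maxPerClass) else r
      }))
      y <- factor(v2[pick], levels = dests)
      wts <- as.numeric(1 / table(y)[y])      # balance by class weight
      capture.output(net <- nnet::nnet(
        x = Xs[pick, , drop = FALSE], y = nnet::class.ind(y),
        weights = wts, size = hiddenSize, softmax = TRUE,
        maxit = maxit, trace = FALSE))
      prob <- stats::predict(net, Xs)
      colnames(prob) <- levels(y)
      for (j in dests[dests != i]) {
        vals <- matrix(NA_real_, nrow(mapT1@values), ncol(mapT1@values))
        vals[ok] <- prob[, as.character(j)]
        nm <- sprintf("%g->%g", i, j)
        pairs[[length(pairs) + 1]] <- data.frame(from = i, to = j)
        pots[[nm]] <- rasterGrid(vals, mask = ok,
                                 origin = gridOrigin(mapT1),
                                 cellSize = cellSize(mapT1))
      }
    }
  })
  new("TransitionPotentialSet",
      pairs = if (length(pairs)) do.call(rbind, pairs) else
        data.frame(from = numeric(0), to = numeric(0)),
      potentials = pots,
      arch = list(hiddenSize = hiddenSize, maxit = maxit,
                  maxPerClass = maxPerClass, seed = seed))
}

#' Integer change demand from a transition matrix
#'
#' Applies the (horizon-scaled) matrix rows to the current class counts
#' and integerises each row's expected destination counts by the
#' largest-remainder rule, so per-class totals are conserved exactly.
#'
#' @param m a [TransitionMatrix-class] scaled to the projection horizon.
#' @param map current categorical [RasterGrid-class].
#' @return integer matrix of cell-count demands (rows = from, cols = to;
#'   the diagonal is persistence).
#' @export
transitionDemand <- function(m, map) {
  cls <- m@classes
  counts <- vapply(cls, function(c) sum(map@values[map@mask] == c), numeric(1))
  D <- matrix(0L, length(cls), length(cls), dimnames = list(cls, cls))
  for (i in seq_along(cls))
    D[i, ] <- .largestRemainder(m@P[i, ], counts[i])
  D
}

#' Allocate demanded transitions onto the map
#'
#' Converts, for each off-diagonal transition in descending demand order,
#' the demanded number of source-class cells with the highest transition
#' potential (uniform potentials when no surface is available; ties
#' broken by a seeded random draw). Each cell converts at most once; all
#' other cells persist, so the total cell count is conserved and the
#' cross-tabulation of (input, output) reproduces the demand exactly.
#' If a class's total outgoing demand exceeds its cell count the demands
#' are scaled down proportionally with a warning.
#'
#' @param map current categorical [RasterGrid-class].
#' @param demand integer demand matrix from [transitionDemand()].
#' @param potentials optional [TransitionPotentialSet-class].
#' @param seed integer seed for tie-breaking.
#' @return the projected categorical [RasterGrid-class].
#' @export
allocateChange <- function(map, demand, potentials = NULL, seed = NULL) {
  cls <- as.numeric(rownames(demand))
  D <- demand
  diag(D) <- 0L
  counts <- vapply(cls, function(c) sum(map@values[map@mask] == c), numeric(1))
  over <- rowSums(D) > counts
  if (any(over)) {
    warning("outgoing demand exceeds class cell count; scaled down proportionally")
    for (i in which(over))
      D[i, ] <- .largestRemainder(D[i, ], counts[i])
  }
  vals <- map@values
  converted <- matrix(FALSE, nrow(vals), ncol(vals))
  ord <- order(-as.vector(D))
  .withSeed(seed, {
    tie <- stats::runif(length(vals))
    for (idx in ord) {
      want <- as.vector(D)[idx]
      if (want == 0) next
      i <- cls[(idx - 1) %% length(cls) + 1]
      j <- cls[(idx - 1) %/% length(cls) + 1]
      cand <- which(map@mask & vals == i & !converted)
      if (!length(cand)) next
      nm <- sprintf("%g->%g", i, j)
      pot <- if (!is.null(potentials) && nm %in% names(potentials@potentials))
        potentials@potentials[[nm]]@values[cand] else rep(0.5, length(cand))
      pot[is.na(pot)] <- 0
      take <- cand[order(-pot, tie[cand])][seq_len(min(want, length(cand)))]
      vals[take] <- j
      converted[take] <- TRUE
    }
  })
  rasterGrid(vals, mask = map@mask, origin = gridOrigin(map),
             cellSize = cellSize(map), categorical = TRUE)
}

#' Percent change between two area vectors
#'
#' `100 * (areaT2 - areaT1) / areaT1`, the range-change arithmetic used
#' throughout the scenario accounting; zero-area classes yield `NA`.
#'
#' @param areaT1,areaT2 numeric area vectors (same units).
#' @return numeric percent changes.
#' @export
areaChange <- function(areaT1, areaT2) {
  ifelse(areaT1 > 0, 100 * (areaT2 - areaT1) / areaT1, NA_real_)
}

#' Class-area change table of two categorical maps
#'
#' The per-class area accounting between two aligned land-cover maps:
#' one row per class with its area at each date and the percent change
#' recomputed from those areas.
#'
#' @param mapT1,mapT2 aligned categorical maps.
#' @param cellArea area of one cell (defaults to `cellSize^2`).
#' @param classes optional class universe.
#' @return data.frame: `class`, `areaT1`, `areaT2`, `percentChange`.
#' @export
classAreaChange <- function(mapT1, mapT2, cellArea = NULL, classes = NULL) {
  if (is.null(cellArea)) cellArea <- cellSize(mapT1)^2
  ok <- gridMask(mapT1) & gridMask(mapT2)
  v1 <- mapT1@values[ok]; v2 <- mapT2@values[ok]
  if (is.null(classes)) classes <- sort(unique(c(v1, v2)))
  a1 <- vapply(classes, function(c) sum(v1 == c) * cellArea, numeric(1))
  a2 <- vapply(classes, function(c) sum(v2 == c) * cellArea, numeric(1))
  data.frame(class = classes, areaT1 = a1, areaT2 = a2,
             percentChange = areaChange(a1, a2))
}
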