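#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# RasterGrid

#' RasterGrid: a single planar raster layer
#'
#' A north-up planar grid of numeric values with a logical validity mask.
#' Row 1 is the northernmost row; `origin` is the (x, y) of the lower-left
#' corner (the ESRI ASCII Grid convention). Cell centres sit at
#' `x0 + (col - 0.5) * cellSize`, `y0 + (nrow - row + 0.5) * cellSize`, and
#' points are binned into cells by half-open intervals
#' `[edge, edge + cellSize)`. Categorical layers store integer class IDs.
#'
#' @slot values numeric matrix; masked cells are `NA`.
#' @slot mask logical matrix of the same shape; `TRUE` = valid.
#' @slot origin numeric(2), x/y of the lower-left grid corner.
#' @slot cellSize positive cell edge length (abstract planar units).
#' @slot categorical logical flag; `TRUE` for integer class-ID layers.
#'
#' @param values numeric matrix.
#' @param mask logical matrix; defaults to `!is.na(values)`.
#' @param origin,cellSize grid geometry.
#' @param categorical logical flag.
#' @param x a `RasterGrid`.
#' @aliases gridValues gridMask cellSize gridOrigin isCategorical
#' @export
setClass("RasterGrid",
  representation(values = "matrix", mask = "matrix", origin = "numeric",
                 cellSize = "numeric", categorical = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (!all(dim(object@values) == dim(object@mask)))
      msg <- c(msg, "values and mask must share their shape")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be logical")
    if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (length(object@origin) != 2L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be two finite numbers")
    if (length(object@categorical) != 1L)
      msg <- c(msg, "categorical must be a single flag")
    if (isTRUE(object@categorical)) {
      v <- object@values[object@mask]
      if (length(v) && any(abs(v - round(v)) > 1e-8))
        msg <- c(msg, "categorical layer holds non-integer class IDs")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname RasterGrid-class
#' @export
rasterGrid <- function(values, mask = NULL, origin = c(0, 0), cellSize = 1,
                       categorical = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(mask)) mask <- !is.na(values)
  mask <- mask & !is.na(values)
  values[!mask] <- NA_real_
  new("RasterGrid", values = values, mask = mask,
      origin = as.numeric(origin), cellSize = as.numeric(cellSize),
      categorical = isTRUE(categorical))
}

setMethod("gridValues", "RasterGrid", function(x) x@values)
setMethod("gridMask", "RasterGrid", function(x) x@mask)
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)
setMethod("gridOrigin", "RasterGrid", function(x) x@origin)
setMethod("isCategorical", "RasterGrid", function(x) x@categorical)

#' @rdname RasterGrid-class
#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("RasterGrid: %d x %d cells (%s), cell size %g, %d valid\n",
              d[1], d[2], if (object@categorical) "categorical" else "continuous",
              object@cellSize, sum(object@mask)))
  v <- object@values[object@mask]
  if (length(v))
    cat(sprintf("  range [%g, %g]\n", min(v), max(v)))
})

# ---------------------------------------------------------------------------
# RasterStack

#' RasterStack: aligned named raster layers
#'
#' An ordered, named collection of [RasterGrid-class] layers sharing grid
#' geometry and a common validity mask. The constructor intersects the
#' layers' masks and reapplies the combined mask to every layer, so that
#' downstream model fitting sees one shared support.
#'
#' @slot layers named list of [RasterGrid-class].
#'
#' @param ... `RasterGrid` layers, named, or a single named list of them.
#' @param x a `RasterStack`.
#' @param name layer name.
#' @aliases layerNames nLayers getLayer
#' @export
setClass("RasterStack", representation(layers = "list"),
  validity = function(object) {
    ls <- object@layers
    if (!length(ls)) return("stack holds no layers")
    if (is.null(names(ls)) || any(!nzchar(names(ls))) || anyDuplicated(names(ls)))
      return("layers must carry unique non-empty names")
    if (!all(vapply(ls, is, logical(1), class2 = "RasterGrid")))
      return("all layers must be RasterGrid objects")
    ref <- ls[[1]]
    for (l in ls) {
      if (!all(dim(l@values) == dim(ref@values)) ||
          any(abs(l@origin - ref@origin) > 1e-9) ||
          abs(l@cellSize - ref@cellSize) > 1e-12)
        return("layers must share shape, origin and cell size")
      if (!identical(l@mask, ref@mask))
        return("layers must share one validity mask")
    }
    TRUE
  })

#' @rdname RasterStack-class
#' @export
rasterStack <- function(...) {
  ls <- list(...)
  if (length(ls) == 1L && is.list(ls[[1]]) && !is(ls[[1]], "RasterGrid"))
    ls <- ls[[1]]
  if (!length(ls)) stop("rasterStack() needs at least one layer")
  d <- dim(ls[[1]]@values)
  if (!all(vapply(ls, function(l) all(dim(l@values) == d), logical(1))))
    stop("layers must share shape, origin and cell size")
  shared <- Reduce(`&`, lapply(ls, function(l) l@mask))
  ls <- lapply(ls, function(l) {
    l@mask <- shared
    l@values[!shared] <- NA_real_
    l
  })
  new("RasterStack", layers = ls)
}

setMethod("layerNames", "RasterStack", function(x) names(x@layers))
setMethod("nLayers", "RasterStack", function(x) length(x@layers))
setMethod("getLayer", "RasterStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop(sprintf("no layer named '%s' in stack", name))
  x@layers[[name]]
})
setMethod("gridMask", "RasterStack", function(x) x@layers[[1]]@mask)
setMethod("cellSize", "RasterStack", function(x) x@layers[[1]]@cellSize)
setMethod("gridOrigin", "RasterStack", function(x) x@layers[[1]]@origin)
setMethod("dim", "RasterStack", function(x) dim(x@layers[[1]]@values))

setMethod("show", "RasterStack", function(object) {
  d <- dim(object)
  cat(sprintf("RasterStack: %d layer(s), %d x %d cells, %d valid\n",
              length(object@layers), d[1], d[2], sum(gridMask(object))))
  flag <- vapply(object@layers, isCategorical, logical(1))
  cat("  ", paste0(names(object@layers), ifelse(flag, "*", ""), collapse = ", "),
      "\n  (* categorical)\n", sep = "")
})

# ---------------------------------------------------------------------------
# OccurrenceSet

#' OccurrenceSet: presence-only point records
#'
#' Planar x/y coordinates of species presence records (or background
#' points), with free-text provenance notes tracking cleaning steps.
#'
#' @slot points two-column numeric matrix (x, y).
#' @slot provenance character vector of processing notes.
#'
#' @param x,y coordinates, or `x` a two-column matrix/data.frame.
#' @param provenance character notes.
#' @aliases coords nOccurrences
#' @export
setClass("OccurrenceSet",
  representation(points = "matrix", provenance = "character"),
  validity = function(object) {
    if (ncol(object@points) != 2L) return("points must have two columns (x, y)")
    if (nrow(object@points) && any(!is.finite(object@points)))
      return("coordinates must be finite")
    TRUE
  })

#' @rdname OccurrenceSet-class
#' @export
occurrenceSet <- function(x, y = NULL, provenance = character(0)) {
  if (is.null(y)) {
    pts <- as.matrix(as.data.frame(x)[, 1:2])
  } else {
    pts <- cbind(x, y)
  }
  storage.mode(pts) <- "double"
  colnames(pts) <- c("x", "y")
  new("OccurrenceSet", points = pts, provenance = as.character(provenance))
}

setMethod("coords", "OccurrenceSet", function(x) x@points)
setMethod("nOccurrences", "OccurrenceSet", function(x) nrow(x@points))
setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d point(s)\n", nrow(object@points)))
  for (p in object@provenance) cat("  - ", p, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# FeatureMatrix

#' FeatureMatrix: expanded model features at a set of cells
#'
#' Holds the design matrix of maxent features (all entries in [0, 1]),
#' the feature definitions that generated it, and per-variable training
#' summaries (scaling bounds, means, modal categorical level) frozen from
#' the data the expansion was built on. Expansions built against a
#' `reference` reuse that reference's definitions and bounds, clamping
#' out-of-range values — the extrapolation rule used for scenario
#' projection.
#'
#' @slot M numeric matrix, rows = cells, columns = features, entries in [0,1].
#' @slot defs data.frame of feature definitions (kind, var, var2, knot,
#'   level, name).
#' @slot varSummary data.frame of per-variable training summaries.
#' @slot classes character, the feature classes requested.
#' @export
setClass("FeatureMatrix",
  representation(M = "matrix", defs = "data.frame",
                 varSummary = "data.frame", classes = "character"),
  validity = function(object) {
    if (ncol(object@M) != nrow(object@defs))
      return("column count must match the number of feature definitions")
    if (length(object@M) && any(!is.finite(object@M)))
      return("feature values must be finite")
    if (length(object@M) && (min(object@M) < -1e-9 || max(object@M) > 1 + 1e-9))
      return("feature values must lie in [0, 1]")
    TRUE
  })

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d cell(s) x %d feature(s) [classes %s]\n",
              nrow(object@M), ncol(object@M),
              paste(object@classes, collapse = "")))
  print(table(object@defs$kind))
})

# ---------------------------------------------------------------------------
# MaxentModel

#' MaxentModel: a fitted L1-regularised maximum-entropy model
#'
#' The Gibbs distribution `q(x) = exp(lambda . f(x)) / Z` over the training
#' background, fitted by greedy coordinate-wise ascent of the penalised
#' log-likelihood. Stores the weights, the log-normaliser, the entropy of
#' the fitted raw distribution (used for the logistic transform), the
#' regularised-gain trajectory and per-feature gain credits (the raw
#' material of percent contribution).
#'
#' @slot lambda named numeric, one weight per feature.
#' @slot beta named numeric, per-feature L1 penalties actually applied.
#' @slot logZ log of the normaliser over the training background.
#' @slot H entropy of the fitted raw distribution over the background.
#' @slot gain final unpenalised training gain (mean presence log-probability
#'   minus log of the uniform background probability).
#' @slot regGain final regularised training gain.
#' @slot gainTrajectory regularised gain after each accepted update.
#' @slot gainCredits named numeric, per-feature accumulated gain changes.
#' @slot defs,varSummary,classes frozen feature expansion (see
#'   [FeatureMatrix-class]).
#' @slot converged logical; `FALSE` if the iteration cap was hit first.
#' @slot iterations number of coordinate updates performed.
#' @slot regMultiplier,config fit settings.
#' @slot nPresence,nBackground training sample sizes.
#'
#' @param x a `MaxentModel`.
#' @aliases lambdas entropy trainingGain regularizedGain isConverged
#' @export
setClass("MaxentModel",
  representation(lambda = "numeric", beta = "numeric", logZ = "numeric",
                 H = "numeric", gain = "numeric", regGain = "numeric",
                 gainTrajectory = "numeric", gainCredits = "numeric",
                 defs = "data.frame", varSummary = "data.frame",
                 classes = "character", converged = "logical",
                 iterations = "numeric", regMultiplier = "numeric",
                 config = "list", nPresence = "numeric",
                 nBackground = "numeric"))

setMethod("lambdas", "MaxentModel", function(x) x@lambda)
setMethod("entropy", "MaxentModel", function(x) x@H)
setMethod("trainingGain", "MaxentModel", function(x) x@gain)
setMethod("regularizedGain", "MaxentModel", function(x) x@regGain)
setMethod("isConverged", "MaxentModel", function(x) x@converged)

setMethod("show", "MaxentModel", function(object) {
  cat(sprintf(paste0("MaxentModel: %d feature(s) (%d active), classes %s, ",
                     "beta multiplier %g\n"),
              length(object@lambda), sum(object@lambda != 0),
              paste(object@classes, collapse = ""), object@regMultiplier))
  cat(sprintf("  gain %.4f (regularised %.4f), entropy %.4f, %s after %d updates\n",
              object@gain, object@regGain, object@H,
              if (object@converged) "converged" else "NOT converged",
              object@iterations))
})

# ---------------------------------------------------------------------------
# TransitionMatrix

#' TransitionMatrix: land-cover class transition probabilities
#'
#' Row-stochastic matrix `P[i, j]` = probability that a class-`i` cell
#' becomes class `j` over `intervalYears`.
#'
#' @slot classes integer class IDs (row/column order).
#' @slot P row-stochastic matrix.
#' @slot intervalYears positive interval length in years.
#' @export
setClass("TransitionMatrix",
  representation(classes = "integer", P = "matrix", intervalYears = "numeric"),
  validity = function(object) {
    if (nrow(object@P) != length(object@classes) ||
        ncol(object@P) != length(object@classes))
      return("P must be square with one row per class")
    if (any(object@P < -1e-12)) return("transition probabilities must be >= 0")
    if (any(abs(rowSums(object@P) - 1) > 1e-9))
      return("each row of P must sum to 1 (within 1e-9)")
    if (object@intervalYears <= 0) return("intervalYears must be positive")
    TRUE
  })

#' @rdname TransitionMatrix-class
#' @param P row-stochastic matrix.
#' @param classes integer class IDs; defaults to `1:nrow(P)` or dimnames.
#' @param intervalYears interval covered by one application of `P`.
#' @export
transitionMatrix <- function(P, classes = NULL, intervalYears = 1) {
  P <- as.matrix(P)
  if (is.null(classes)) {
    classes <- if (!is.null(rownames(P))) as.integer(rownames(P)) else seq_len(nrow(P))
  }
  dimnames(P) <- list(classes, classes)
  new("TransitionMatrix", classes = as.integer(classes), P = P,
      intervalYears = as.numeric(intervalYears))
}

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix: %d classes over %g year(s)\n",
              length(object@classes), object@intervalYears))
  print(round(object@P, 4))
})

# ---------------------------------------------------------------------------
# TransitionPotentialSet

#' TransitionPotentialSet: per-transition suitability-for-change surfaces
#'
#' One potential raster in [0, 1] per modelled class-to-class transition,
#' produced by per-source-class multi-layer perceptrons on driver
#' variables, plus the architecture descriptor used to train them.
#'
#' @slot pairs data.frame with columns `from`, `to`.
#' @slot potentials named list of [RasterGrid-class] ("from->to").
#' @slot arch list describing the MLP (hidden size, maxit, seed).
#' @export
setClass("TransitionPotentialSet",
  representation(pairs = "data.frame", potentials = "list", arch = "list"))

setMethod("show", "TransitionPotentialSet", function(object) {
  cat(sprintf("TransitionPotentialSet: %d modelled transition(s)\n",
              nrow(object@pairs)))
  if (nrow(object@pairs))
    cat("  ", paste(object@pairs$from, "->", object@pairs$to, collapse = ", "),
        "\n", sep = "")
})

# ---------------------------------------------------------------------------
# ReplicateSet

#' ReplicateSet: bootstrap-replicated model fits and suitability maps
#'
#' Models fitted on seeded random train/test partitions of the occurrence
#' records, their per-replicate logistic suitability maps, and the
#' cell-wise mean map used for thresholding and scenario projection.
#'
#' @slot models list of [MaxentModel-class], one per replicate.
#' @slot maps list of [RasterGrid-class] logistic maps, one per replicate.
#' @slot meanMap cell-wise mean of the replicate maps.
#' @slot partitions list of lists with integer `train` / `test` indices.
#' @slot aucTrain,aucTest per-replicate rank AUC (test `NA` when empty).
#' @slot trainSuitability logistic suitability of training presences,
#'   pooled over replicates (input to the ten-percentile threshold).
#' @slot settings list: feature classes, regularisation multiplier, n,
#'   train fraction, resampling method, seed.
#' @export
setClass("ReplicateSet",
  representation(models = "list", maps = "list", meanMap = "RasterGrid",
                 partitions = "list", aucTrain = "numeric",
                 aucTest = "numeric", trainSuitability = "numeric",
                 settings = "list"))

setMethod("show", "ReplicateSet", function(object) {
  cat(sprintf("ReplicateSet: %d replicate(s), classes %s, beta %g\n",
              length(object@models),
              paste(object@settings$classes, collapse = ""),
              object@settings$regMultiplier))
  cat(sprintf("  mean train AUC %.3f, mean test AUC %.3f\n",
              mean(object@aucTrain), mean(object@aucTest, na.rm = TRUE)))
})

# ---------------------------------------------------------------------------
# ThresholdedMap / ScenarioResult

#' ThresholdedMap: binary suitable/unsuitable map at a fixed threshold
#'
#' @slot threshold the suitability cutoff (cells with suitability >=
#'   threshold are suitable).
#' @slot binary categorical [RasterGrid-class] of 0/1.
#' @slot suitableCount number of suitable unmasked cells.
#' @slot suitableFraction fraction of unmasked cells that are suitable.
#' @export
setClass("ThresholdedMap",
  representation(threshold = "numeric", binary = "RasterGrid",
                 suitableCount = "numeric", suitableFraction = "numeric"))

setMethod("show", "ThresholdedMap", function(object) {
  cat(sprintf("ThresholdedMap: threshold %.4g, %d suitable cell(s) (%.1f%%)\n",
              object@threshold, object@suitableCount,
              100 * object@suitableFraction))
})

#' ScenarioResult: projected suitability under one scenario
#'
#' @slot label scenario label (e.g. "current" or a GCM x RCP tag).
#' @slot suitability mean logistic suitability map under the scenario.
#' @slot thresholded [ThresholdedMap-class] at the current-data threshold.
#' @slot percentChange percent change in suitable area versus the current
#'   baseline: `100 * (future - current) / current`.
#' @export
setClass("ScenarioResult",
  representation(label = "character", suitability = "RasterGrid",
                 thresholded = "ThresholdedMap", percentChange = "numeric"))

setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf("ScenarioResult '%s': %d suitable cell(s), range change %+.2f%%\n",
              object@label, object@thresholded@suitableCount,
              object@percentChange))
})
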