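#' @include AllClasses.R
NULL

#' Replicated model fits on random train/test partitions
#'
#' Runs `n` seeded replicates: each draws a random 75/25 (by default)
#' train/validation partition of the occurrence records, fits the
#' selected specification on the training part against the full
#' background, and predicts the logistic suitability of every landscape
#' cell. The cell-wise mean of the replicate maps is the working
#' suitability surface. `method = "subsample"` splits without
#' replacement so every occurrence lands in exactly one side of the
#' partition; `method = "bootstrap"` draws the training set with
#' replacement (validation = out-of-bag records).
#'
#' @param presences cleaned presence [OccurrenceSet-class].
#' @param background background [OccurrenceSet-class].
#' @param stack current predictor [RasterStack-class].
#' @param classes feature classes of the selected specification.
#' @param regMultiplier selected regularisation multiplier.
#' @param n number of replicates (default 20).
#' @param trainFrac training fraction (default 0.75).
#' @param method "subsample" (default) or "bootstrap".
#' @param knots,config expansion and fit settings.
#' @param seed integer seed driving every partition.
#' @return a [ReplicateSet-class].
#' @export
runReplicates <- function(presences, background, stack,
                          classes = c("L", "Q"), regMultiplier = 1,
                          n = 20, trainFrac = 0.75,
                          method = c("subsample", "bootstrap"),
                          knots = 10, config = fitConfig(), seed = NULL) {
  method <- match.arg(method)
  stopifnot(n >= 1, trainFrac > 0, trainFrac <= 1)
  presData <- extractValues(stack, presences)
  ok <- stats::complete.cases(presData)
  presData <- presData[ok, , drop = FALSE]
  np <- nrow(presData)
  if (np < 1) stop("no presences fall on valid cells")
  bgData <- extractValues(stack, background)
  bgData <- bgData[stats::complete.cases(bgData), , drop = FALSE]
  attr(bgData, "categorical") <- attr(presData, "categorical")
  bgF <- expandFeatures(bgData, classes = classes,
                        categorical = attr(bgData, "categorical"),
                        knots = knots)
  landDf <- cellTable(stack)
  landF <- expandFeatures(landDf, reference = bgF)
  mask <- gridMask(stack)

  partitions <- .withSeed(seed, lapply(seq_len(n), function(r) {
    if (method == "bootstrap") {
      tr <- sort(sample.int(np, np, replace = TRUE))
      list(train = tr, test = setdiff(seq_len(np), unique(tr)))
    } else {
      ntr <- max(1L, floor(trainFrac * np))
      tr <- sort(sample.int(np, ntr))
      list(train = tr, test = setdiff(seq_len(np), tr))
    }
  }))

  models <- vector("list", n); maps <- vector("list", n)
  aucTrain <- aucTest <- numeric(n)
  trainSuit <- numeric(0)
  bgScoresOf <- function(model) predictLogistic(model, bgF)
  for (r in seq_len(n)) {
    part <- partitions[[r]]
    if (!length(part$train)) stop("empty training partition")
    presF <- expandFeatures(presData[part$train, , drop = FALSE],
                            reference = bgF)
    model <- fitMaxent(presF, bgF, regMultiplier = regMultiplier,
                       config = config)
    suitLand <- predictLogistic(model, landF)
    vals <- matrix(NA_real_, nrow(mask), ncol(mask))
    vals[attr(landDf, "cell")] <- suitLand
    maps[[r]] <- rasterGrid(vals, mask = mask, origin = gridOrigin(stack),
                            cellSize = cellSize(stack))
    sTrain <- predictLogistic(model, presF)
    sBg <- bgScoresOf(model)
    aucTrain[r] <- rankAUC(sTrain, sBg)
    aucTest[r] <- if (length(part$test))
      rankAUC(predictLogistic(model,
                              expandFeatures(presData[part$test, , drop = FALSE],
                                             reference = bgF)), sBg)
      else NA_real_
    trainSuit <- c(trainSuit, sTrain)
    models[[r]] <- model
  }
  meanVals <- Reduce(`+`, lapply(maps, gridValues)) / n
  meanMap <- rasterGrid(meanVals, mask = mask, origin = gridOrigin(stack),
                        cellSize = cellSize(stack))
  new("ReplicateSet", models = models, maps = maps, meanMap = meanMap,
      partitions = partitions, aucTrain = aucTrain, aucTest = aucTest,
      trainSuitability = trainSuit,
      settings = list(classes = classes, regMultiplier = regMultiplier,
                      n = n, trainFrac = trainFrac, method = method,
                      knots = knots, seed = seed))
}

#' Ten-percentile training presence threshold
#'
#' The suitability value at the ascending order statistic of rank
#' `ceiling(0.10 * n)` of the training-presence suitabilities: the
#' binarisation cutoff that omits (at most) the lowest 10% of training
#' presences. No interpolation is used, so the threshold is always an
#' observed suitability value.
#'
#' @param trainingSuitability suitability of the training presences.
#' @param percentile omission percentile (default 0.10).
#' @return the threshold value.
#' @export
tenPercentileThreshold <- function(trainingSuitability, percentile = 0.10) {
  x <- trainingSuitability[!is.na(trainingSuitability)]
  if (!length(x)) stop("no training suitability values")
  sort(x)[ceiling(percentile * length(x))]
}

#' Binarise a suitability map at a threshold
#'
#' Cells with suitability >= the threshold are suitable (1), the rest
#' unsuitable (0); the suitable cell count and its fraction of the
#' unmasked area are reported alongside.
#'
#' @param map continuous suitability [RasterGrid-class].
#' @param threshold the cutoff (e.g. from [tenPercentileThreshold()]).
#' @return a [ThresholdedMap-class].
#' @export
binarizeMap <- function(map, threshold) {
  stopifnot(is.finite(threshold))
  vals <- ifelse(map@mask, as.numeric(map@values >= threshold), NA_real_)
  nSuit <- sum(vals == 1, na.rm = TRUE)
  new("ThresholdedMap", threshold = threshold,
      binary = rasterGrid(vals, mask = map@mask, origin = gridOrigin(map),
                          cellSize = cellSize(map), categorical = TRUE),
      suitableCount = nSuit,
      suitableFraction = nSuit / sum(map@mask))
}

#' Project the replicate models onto a scenario stack
#'
#' Predicts each replicate model on the scenario predictor stack (future
#' climate layers and simulated land cover; values outside the training
#' range are clamped), averages the maps, binarises at the
#' **current-data** threshold, and reports the percent range change
#' against the current binary map:
#' `100 * (suitable_future - suitable_current) / suitable_current`.
#'
#' @param replicates a [ReplicateSet-class].
#' @param futureStack scenario [RasterStack-class] carrying every
#'   predictor of the fitted models.
#' @param label scenario label.
#' @param threshold the current-data ten-percentile threshold.
#' @param current the current [ThresholdedMap-class] baseline.
#' @return a [ScenarioResult-class].
#' @export
projectScenario <- function(replicates, futureStack, label, threshold,
                            current) {
  need <- unique(replicates@models[[1]]@varSummary$var)
  missing <- setdiff(need, layerNames(futureStack))
  if (length(missing))
    stop(sprintf("future stack lacks predictor(s): %s",
                 paste(missing, collapse = ", ")))
  df <- cellTable(futureStack)
  mask <- gridMask(futureStack)
  acc <- NULL
  for (model in replicates@models) {
    p <- predictLogistic(model, df)
    acc <- if (is.null(acc)) p else acc + p
  }
  vals <- matrix(NA_real_, nrow(mask), ncol(mask))
  vals[attr(df, "cell")] <- acc / length(replicates@models)
  suit <- rasterGrid(vals, mask = mask, origin = gridOrigin(futureStack),
                     cellSize = cellSize(futureStack))
  thr <- binarizeMap(suit, threshold)
  delta <- areaChange(current@suitableCount, thr@suitableCount)
  new("ScenarioResult", label = label, suitability = suit,
      thresholded = thr, percentChange = delta)
}

#' Scenario summary table
#'
#' One row per scenario with the suitable areas and percent range
#' change, in the shape of a published range-change table.
#'
#' @param current the current [ThresholdedMap-class].
#' @param scenarios list of [ScenarioResult-class].
#' @param cellArea area of one cell.
#' @return data.frame: scenario, suitableAreaCurrent, suitableAreaFuture,
#'   percentChange.
#' @export
scenarioTable <- function(current, scenarios, cellArea = 1) {
  data.frame(
    scenario = vapply(scenarios, function(s) s@label, character(1)),
    suitableAreaCurrent = current@suitableCount * cellArea,
    suitableAreaFuture = vapply(scenarios, function(s)
      s@thresholded@suitableCount * cellArea, numeric(1)),
    percentChange = vapply(scenarios, function(s) s@percentChange, numeric(1)))
}
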