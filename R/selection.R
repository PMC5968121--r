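#' @include AllClasses.R
NULL

#' Enumerate candidate model specifications
#'
#' The Cartesian product of every non-empty subset of the feature classes
#' with every regularisation multiplier: the default grids (all subsets of
#' L, Q, H, P, T; multipliers 0.1 and 1..10) give 31 x 11 = 341
#' candidates.
#'
#' @param featureClasses classes to combine (default L, Q, H, P, T).
#' @param regGrid regularisation multipliers (default `c(0.1, 1:10)`).
#' @return data.frame with columns `features` (collapsed class string,
#'   e.g. "LQ") and `regMultiplier`.
#' @export
enumerateCandidates <- function(featureClasses = c("L", "Q", "H", "P", "T"),
                                regGrid = c(0.1, 1:10)) {
  stopifnot(length(featureClasses) >= 1, length(regGrid) >= 1)
  featureClasses <- unique(featureClasses)
  subsets <- unlist(lapply(seq_along(featureClasses), function(k)
    utils::combn(featureClasses, k, paste, collapse = "", simplify = FALSE)))
  out <- expand.grid(features = unlist(subsets), regMultiplier = regGrid,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out[order(match(out$features, subsets), out$regMultiplier), , drop = FALSE]
}

#' Small-sample-corrected AIC of a fitted model
#'
#' Raw model scores are standardised to sum to 1 over all landscape
#' cells; the log-likelihood is the summed log standardised probability
#' at the occurrence cells; `k` counts features with nonzero weight; and
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)`. Candidates with
#' `n <= k + 1` are flagged invalid (non-finite AICc).
#'
#' @param model a [MaxentModel-class].
#' @param occurrences data.frame of raw predictor values at the `n`
#'   occurrence cells (or a [FeatureMatrix-class]).
#' @param landscape data.frame of raw predictor values at every landscape
#'   cell (or a [FeatureMatrix-class] / [RasterStack-class]).
#' @return one-row data.frame: `k`, `lnL`, `AICc`, `valid`.
#' @export
computeAICc <- function(model, occurrences, landscape) {
  if (is(landscape, "RasterStack")) landscape <- cellTable(landscape)
  sOcc <- .modelScores(model, occurrences)
  sLand <- .modelScores(model, landscape)
  logZL <- .logSumExp(sLand)
  n <- length(sOcc)
  lnL <- sum(sOcc) - n * logZL
  k <- sum(model@lambda != 0)
  valid <- n > k + 1
  aicc <- if (valid) -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  data.frame(k = k, lnL = lnL, AICc = aicc, valid = valid)
}

#' Select the lowest-AICc candidate
#'
#' Returns the valid candidate with minimal AICc; ties are broken by
#' smaller `k`, then smaller regularisation multiplier, then
#' lexicographic feature-class string. Permutation-invariant in the score
#' order.
#'
#' @param scores data.frame with columns `features`, `regMultiplier`,
#'   `k`, `AICc`, `valid` (the shape produced by [tuneMaxent()]).
#' @return the selected row of `scores`.
#' @export
selectBestModel <- function(scores) {
  ok <- scores[which(scores$valid & is.finite(scores$AICc)), , drop = FALSE]
  if (!nrow(ok)) stop("no valid candidates to select from")
  sortKey <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  ord <- order(ok$AICc, ok$k, ok$regMultiplier,
               vapply(ok$features, sortKey, character(1)))
  ok[ord[1], , drop = FALSE]
}

#' Tune feature classes and regularisation by AICc
#'
#' Fits every candidate specification on the full occurrence set (the
#' train/test partitioning happens downstream, in the replicate runs),
#' scores each by [computeAICc()], and selects the least-overfit model.
#'
#' @param presenceData,backgroundData data.frames of raw predictor values
#'   at the presence and background cells (see [extractValues()]).
#' @param landscape data.frame of raw values at all landscape cells, or a
#'   [RasterStack-class]; defaults to the background cells.
#' @param featureClasses,regGrid candidate grids
#'   (see [enumerateCandidates()]).
#' @param knots T/H knots per variable.
#' @param config a [fitConfig()].
#' @param verbose print progress.
#' @return list with the score `table` (one row per candidate, columns
#'   features, regMultiplier, k, lnL, AICc, valid, selected), the `best`
#'   row, and the refitted best `model`.
#' @export
tuneMaxent <- function(presenceData, backgroundData, landscape = NULL,
                       featureClasses = c("L", "Q", "H", "P", "T"),
                       regGrid = c(0.1, 1:10), knots = 10,
                       config = fitConfig(), verbose = FALSE) {
  if (is.null(landscape)) landscape <- backgroundData
  if (is(landscape, "RasterStack")) landscape <- cellTable(landscape)
  cand <- enumerateCandidates(featureClasses, regGrid)
  cat0 <- attr(backgroundData, "categorical")
  rows <- vector("list", nrow(cand))
  fms <- list()   # cache expansions per feature subset
  for (i in seq_len(nrow(cand))) {
    fs <- cand$features[i]
    if (is.null(fms[[fs]])) {
      cl <- strsplit(fs, "")[[1]]
      bg <- expandFeatures(backgroundData, classes = cl, categorical = cat0,
                           knots = knots)
      fms[[fs]] <- list(
        bg = bg,
        pres = expandFeatures(presenceData, reference = bg),
        land = expandFeatures(landscape, reference = bg))
    }
    e <- fms[[fs]]
    fit <- fitMaxent(e$pres, e$bg, regMultiplier = cand$regMultiplier[i],
                     config = config)
    sc <- computeAICc(fit, e$pres, e$land)
    rows[[i]] <- cbind(cand[i, , drop = FALSE], sc)
    if (verbose)
      message(sprintf("candidate %s beta=%g: k=%d AICc=%.2f", fs,
                      cand$regMultiplier[i], sc$k, sc$AICc))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  best <- selectBestModel(table)
  table$selected <- seq_len(nrow(table)) %in%
    which(table$features == best$features &
            table$regMultiplier == best$regMultiplier)[1]
  e <- fms[[best$features]]
  model <- fitMaxent(e$pres, e$bg, regMultiplier = best$regMultiplier,
                     config = config)
  list(table = table, best = best, model = model)
}
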