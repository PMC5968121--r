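#' @include AllClasses.R
NULL

#' Rank-based AUC
#'
#' The Mann-Whitney probability that a randomly chosen presence outranks
#' a randomly chosen background point under the model's scores, with ties
#' counting one half. 0.5 is the random-chance anchor; 1 is perfect
#' separation.
#'
#' @param presenceScores,backgroundScores numeric score vectors.
#' @return AUC in [0, 1].
#' @export
rankAUC <- function(presenceScores, backgroundScores) {
  np <- length(presenceScores); nb <- length(backgroundScores)
  if (!np || !nb) stop("both score sets must be non-empty")
  r <- rank(c(presenceScores, backgroundScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Qualitative AUC band
#'
#' The conventional model-performance labels: 0.5-0.6 Failed, 0.6-0.7
#' Poor, 0.7-0.8 Fair, 0.8-0.9 Good, 0.9-1 Excellent, with band
#' boundaries assigned to the upper band; values below 0.5 are labelled
#' "worse than random".
#'
#' @param auc AUC value in [0, 1].
#' @return character label.
#' @export
aucBand <- function(auc) {
  stopifnot(auc >= 0, auc <= 1)
  if (auc < 0.5) return("worse than random")
  if (auc < 0.6) return("Failed")
  if (auc < 0.7) return("Poor")
  if (auc < 0.8) return("Fair")
  if (auc < 0.9) return("Good")
  "Excellent"
}

#' Continuous Boyce Index
#'
#' Slides `windowCount` overlapping windows of width
#' `windowFraction * range` across the landscape suitability range. Per
#' window, `P` is the fraction of presences and `E` the fraction of
#' landscape cells falling inside; windows with `E = 0` are dropped. The
#' index is the Spearman rank correlation between the
#' predicted-to-expected ratio `P/E` and the window midpoint: +1 means
#' presences concentrate monotonically in high-suitability cells, 0 a
#' random model, negative counter-prediction. Because it is rank-based it
#' is invariant under strictly monotone transforms of the scores.
#'
#' @param presenceSuitability suitability at presence points.
#' @param landscapeSuitability suitability of all landscape cells.
#' @param windowCount number of overlapping windows (default 101).
#' @param windowFraction window width as a fraction of the suitability
#'   range (default 0.1).
#' @return list of class `boyceResult`: `midpoints`, `PE`, `CBI`,
#'   `windowCount`, `windowWidth`.
#' @export
boyceIndex <- function(presenceSuitability, landscapeSuitability,
                       windowCount = 101, windowFraction = 0.1) {
  if (!length(presenceSuitability) || !length(landscapeSuitability))
    stop("both suitability vectors must be non-empty")
  lo <- min(landscapeSuitability); hi <- max(landscapeSuitability)
  if (hi <= lo) stop("landscape suitability has zero range")
  w <- windowFraction * (hi - lo)
  mids <- seq(lo + w / 2, hi - w / 2, length.out = windowCount)
  P <- E <- numeric(windowCount)
  for (i in seq_len(windowCount)) {
    lo_i <- mids[i] - w / 2; hi_i <- mids[i] + w / 2
    P[i] <- mean(presenceSuitability >= lo_i & presenceSuitability <= hi_i)
    E[i] <- mean(landscapeSuitability >= lo_i & landscapeSuitability <= hi_i)
  }
  keep <- E > 0
  if (sum(keep) < 3)
    stop("fewer than 3 usable windows; Boyce correlation undefined")
  pe <- P[keep] / E[keep]
  cbi <- stats::cor(pe, mids[keep], method = "spearman")
  structure(list(midpoints = mids[keep], PE = pe, CBI = cbi,
                 windowCount = windowCount, windowWidth = w),
            class = "boyceResult")
}

#' @export
print.boyceResult <- function(x, ...) {
  cat(sprintf("Continuous Boyce Index: %.3f over %d usable window(s) (width %.3g)\n",
              x$CBI, length(x$PE), x$windowWidth))
  invisible(x)
}

#' Jackknife variable importance
#'
#' Refits the model once with each variable omitted and once with each
#' variable alone (same feature classes and regularisation), reporting
#' unpenalised training gains next to the full-model gain. A variable
#' whose omission barely lowers the gain is redundant given the others; a
#' variable whose solo gain approaches the full gain carries most of the
#' signal by itself.
#'
#' @param presenceData,backgroundData data.frames of raw predictor values.
#' @param classes feature classes of the selected specification.
#' @param regMultiplier selected regularisation multiplier.
#' @param knots,config expansion and fit settings.
#' @return list with `fullGain` and a data.frame `table` (variable,
#'   gainWithout, gainAlone).
#' @export
jackknifeGains <- function(presenceData, backgroundData, classes = c("L", "Q"),
                           regMultiplier = 1, knots = 10,
                           config = fitConfig()) {
  vars <- names(backgroundData)
  if (length(vars) < 2) stop("jackknife needs at least two variables")
  cats <- attr(backgroundData, "categorical")
  fitOn <- function(v) {
    bg <- backgroundData[, v, drop = FALSE]
    attr(bg, "categorical") <- intersect(cats, v)
    pr <- presenceData[, v, drop = FALSE]
    bgF <- expandFeatures(bg, classes = classes,
                          categorical = intersect(cats, v), knots = knots)
    fitMaxent(expandFeatures(pr, reference = bgF), bgF,
              regMultiplier = regMultiplier, config = config)
  }
  full <- fitOn(vars)
  tab <- data.frame(variable = vars,
                    gainWithout = vapply(vars, function(v)
                      trainingGain(fitOn(setdiff(vars, v))), numeric(1)),
                    gainAlone = vapply(vars, function(v)
                      trainingGain(fitOn(v)), numeric(1)),
                    row.names = NULL)
  list(fullGain = trainingGain(full), table = tab)
}

#' Percent contribution of each predictor variable
#'
#' Accumulates the per-update gain credits recorded during fitting over
#' each feature's source variable (product features split their credit
#' evenly between both parents), clamps negative totals at zero, and
#' normalises to sum to 100. With zero total gain the contribution is
#' uniform, with a warning.
#'
#' @param model a [MaxentModel-class].
#' @return named numeric vector of percentages summing to 100.
#' @export
percentContribution <- function(model) {
  vars <- unique(model@varSummary$var)
  tot <- stats::setNames(numeric(length(vars)), vars)
  for (j in seq_len(nrow(model@defs))) {
    d <- model@defs[j, ]
    cr <- model@gainCredits[j]
    if (d$kind == "P") {
      tot[d$var] <- tot[d$var] + cr / 2
      tot[d$var2] <- tot[d$var2] + cr / 2
    } else {
      tot[d$var] <- tot[d$var] + cr
    }
  }
  tot <- pmax(tot, 0)
  if (sum(tot) <= 0) {
    warning("zero total gain; contributions are uniform")
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * tot / sum(tot)
}

#' Evaluation report of a replicate run
#'
#' Bundles the standard evaluation battery: mean train/test rank AUC with
#' its qualitative band, the Continuous Boyce Index of the mean map, the
#' jackknife gain table, and percent variable contributions (averaged
#' over replicate models).
#'
#' @param replicates a [ReplicateSet-class].
#' @param stack the current predictor [RasterStack-class].
#' @param presences the (cleaned) presence [OccurrenceSet-class].
#' @param background the background [OccurrenceSet-class].
#' @param knots,config expansion and fit settings for the jackknife
#'   refits.
#' @return list of class `evaluationReport`.
#' @export
evaluateModel <- function(replicates, stack, presences, background,
                          knots = 10, config = fitConfig()) {
  meanMap <- replicates@meanMap
  presSuit <- meanMap@values[cellFromXY(meanMap, coords(presences))]
  landSuit <- meanMap@values[gridMask(meanMap)]
  cbi <- boyceIndex(presSuit[!is.na(presSuit)], landSuit)
  presData <- extractValues(stack, presences)
  bgData <- extractValues(stack, background)
  jack <- jackknifeGains(presData, bgData,
                         classes = replicates@settings$classes,
                         regMultiplier = replicates@settings$regMultiplier,
                         knots = knots, config = config)
  contribs <- rowMeans(vapply(replicates@models, percentContribution,
                              numeric(nrow(replicates@models[[1]]@varSummary))))
  aucTrain <- mean(replicates@aucTrain)
  aucTest <- mean(replicates@aucTest, na.rm = TRUE)
  structure(list(aucTrain = aucTrain, aucTest = aucTest,
                 aucBand = aucBand(aucTest), CBI = cbi$CBI, boyce = cbi,
                 jackknife = jack, percentContribution = contribs),
            class = "evaluationReport")
}

#' @export
print.evaluationReport <- function(x, ...) {
  cat(sprintf("AUC train %.3f / test %.3f (%s), CBI %.3f\n",
              x$aucTrain, x$aucTest, x$aucBand, x$CBI))
  cat("Percent contribution:\n")
  print(round(sort(x$percentContribution, decreasing = TRUE), 1))
  invisible(x)
}

#' Write an evaluation report as CSV + JSON
#'
#' @param report an `evaluationReport` from [evaluateModel()].
#' @param prefix path prefix; writes `<prefix>.json`,
#'   `<prefix>_jackknife.csv` and `<prefix>_contributions.csv`.
#' @export
writeEvaluationReport <- function(report, prefix) {
  jsonlite::write_json(
    list(aucTrain = report$aucTrain, aucTest = report$aucTest,
         aucBand = report$aucBand, CBI = report$CBI),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$jackknife$table, paste0(prefix, "_jackknife.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(variable = names(report$percentContribution),
                              contribution = unname(report$percentContribution)),
                   paste0(prefix, "_contributions.csv"), row.names = FALSE)
  invisible(prefix)
}
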