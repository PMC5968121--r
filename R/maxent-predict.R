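#' @include AllClasses.R
NULL

# Scores lambda . f(x) for arbitrary newdata, reusing the model's frozen
# feature definitions (with clamping outside the training bounds).
.modelScores <- function(object, newdata) {
  fm <- if (is(newdata, "FeatureMatrix")) {
    if (!identical(newdata@defs$name, object@defs$name))
      stop("newdata was expanded with different feature definitions")
    newdata
  } else if (is(newdata, "RasterStack")) {
    expandFeatures(cellTable(newdata), reference = object)
  } else {
    expandFeatures(as.data.frame(newdata), reference = object)
  }
  as.vector(fm@M %*% object@lambda)
}

#' @rdname predictRaw
#' @export
setMethod("predictRaw", "MaxentModel", function(object, newdata, ...) {
  if (is(newdata, "RasterStack"))
    return(.predictGrid(object, newdata, type = "raw"))
  exp(.modelScores(object, newdata) - object@logZ)
})

#' @rdname predictLogistic
#' @export
setMethod("predictLogistic", "MaxentModel", function(object, newdata, ...) {
  if (is(newdata, "RasterStack"))
    return(.predictGrid(object, newdata, type = "logistic"))
  # c q / (1 + c q) with c = exp(H), computed in log space
  stats::plogis(object@H + .modelScores(object, newdata) - object@logZ)
})

.predictGrid <- function(object, stack, type) {
  df <- cellTable(stack)
  p <- if (type == "raw") predictRaw(object, df) else predictLogistic(object, df)
  mask <- gridMask(stack)
  vals <- matrix(NA_real_, nrow(mask), ncol(mask))
  vals[attr(df, "cell")] <- p
  rasterGrid(vals, mask = mask, origin = gridOrigin(stack),
             cellSize = cellSize(stack))
}

#' Marginal response curve of one predictor
#'
#' Sweeps a single variable across its training range (continuous) or its
#' observed levels (categorical) while every other continuous variable is
#' held at its training-background mean and every other categorical
#' variable at its modal class, and returns the logistic suitability
#' along the sweep.
#'
#' @param model a [MaxentModel-class].
#' @param variable variable name.
#' @param n number of sweep points (continuous variables).
#' @return data.frame with columns `value` and `suitability`.
#' @export
responseCurve <- function(model, variable, n = 100) {
  vs <- model@varSummary
  if (!variable %in% vs$var)
    stop(sprintf("unknown variable '%s'", variable))
  row <- vs[vs$var == variable, ]
  sweep <- if (row$categorical) {
    sort(unique(model@defs$level[model@defs$var == variable &
                                   model@defs$kind == "C"]))
  } else {
    seq(row$lo, row$hi, length.out = n)
  }
  base <- as.data.frame(lapply(seq_len(nrow(vs)), function(i) {
    if (vs$categorical[i]) rep(vs$modalLevel[i], length(sweep))
    else rep(vs$meanValue[i], length(sweep))
  }))
  names(base) <- vs$var
  base[[variable]] <- sweep
  data.frame(value = sweep,
             suitability = predictLogistic(model, base))
}

#' Serialise / restore a fitted model as a plain-text lambdas file
#'
#' A structured header (log-normaliser, entropy, gain, settings) followed
#' by one line per feature: definition fields, weight, and the source
#' variable's scaling bounds.
#'
#' @param model a [MaxentModel-class].
#' @param path output path.
#' @return `writeLambdas()` the path invisibly; `readLambdas()` a list
#'   with the header fields, the feature table, and the variable summary.
#' @export
writeLambdas <- function(model, path) {
  hdr <- c(sprintf("# nichecast maxent model"),
           sprintf("logZ %.17g", model@logZ),
           sprintf("entropy %.17g", model@H),
           sprintf("gain %.17g", model@gain),
           sprintf("regMultiplier %.17g", model@regMultiplier),
           sprintf("nPresence %d", as.integer(model@nPresence)),
           sprintf("nBackground %d", as.integer(model@nBackground)),
           sprintf("classes %s", paste(model@classes, collapse = "")))
  tab <- cbind(model@defs, lambda = unname(model@lambda),
               lo = model@varSummary$lo[match(model@defs$var, model@varSummary$var)],
               hi = model@varSummary$hi[match(model@defs$var, model@varSummary$var)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname writeLambdas
#' @export
readLambdas <- function(path) {
  lines <- readLines(path)
  nHead <- 8L
  kv <- strsplit(lines[2:nHead], " ")
  header <- stats::setNames(lapply(kv, function(x) {
    v <- paste(x[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  }), vapply(kv, `[`, character(1), 1))
  tab <- utils::read.table(text = lines[-seq_len(nHead)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  list(header = header, features = tab)
}
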