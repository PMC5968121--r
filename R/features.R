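#' @include AllClasses.R
NULL

#' Expand raw predictor values into maxent features
#'
#' Builds the basis functions of the maximum-entropy model from raw
#' predictor values at a set of cells. With scaled value
#' `s = (v - lo) / (hi - lo)` (bounds frozen from the training support and
#' clamped to [0, 1] outside them):
#' \itemize{
#'   \item L (linear): `s`
#'   \item Q (quadratic): `s^2`
#'   \item P (product): `s_a * s_b` for every pair of continuous variables
#'   \item T (threshold): step indicator `v > knot`
#'   \item H (hinge): `max(0, v - knot) / (hi - knot)`
#' }
#' T/H knots sit at `knots` equally spaced interior quantiles of the
#' training values. Categorical variables always expand to one indicator
#' column per observed level (class C), regardless of the requested
#' feature classes. Constant variables generate no features (warning).
#'
#' When `reference` is supplied (a [FeatureMatrix-class] or
#' [MaxentModel-class]), its definitions, bounds and levels are reused and
#' new values are clamped into the training range — the projection rule
#' for scenario stacks.
#'
#' @param data data.frame of raw predictor values (one row per cell); a
#'   `categorical` attribute or the `categorical` argument names the
#'   categorical columns.
#' @param classes feature classes to build, subset of L, Q, P, T, H.
#' @param categorical character vector of categorical column names.
#' @param knots number of T/H knots per variable (default 10).
#' @param reference optional object carrying frozen definitions.
#' @return a [FeatureMatrix-class].
#' @export
expandFeatures <- function(data, classes = c("L", "Q"),
                           categorical = attr(data, "categorical"),
                           knots = 10, reference = NULL) {
  data <- as.data.frame(data)
  if (is.null(categorical)) categorical <- character(0)
  if (!is.null(reference)) {
    return(.expandFromReference(data, reference))
  }
  classes <- unique(match.arg(classes, c("L", "Q", "P", "T", "H"),
                              several.ok = TRUE))
  vars <- names(data)
  contVars <- setdiff(vars, categorical)

  vs <- data.frame(var = vars,
                   categorical = vars %in% categorical,
                   lo = NA_real_, hi = NA_real_,
                   meanValue = NA_real_, modalLevel = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_along(vars)) {
    v <- data[[vars[i]]]
    if (any(!is.finite(v))) stop(sprintf("non-finite values in variable '%s'", vars[i]))
    if (vs$categorical[i]) {
      tab <- table(v)
      vs$modalLevel[i] <- as.numeric(names(tab)[which.max(tab)])
    } else {
      vs$lo[i] <- min(v); vs$hi[i] <- max(v)
      vs$meanValue[i] <- mean(v)
    }
  }

  defs <- list()
  addDef <- function(kind, var, var2 = NA, knot = NA, level = NA) {
    defs[[length(defs) + 1]] <<- data.frame(kind = kind, var = var,
                                            var2 = var2, knot = knot,
                                            level = level,
                                            stringsAsFactors = FALSE)
  }
  constVars <- contVars[vs$lo[match(contVars, vs$var)] ==
                          vs$hi[match(contVars, vs$var)]]
  if (length(constVars))
    warning(sprintf("constant variable(s) generate no features: %s",
                    paste(constVars, collapse = ", ")))
  useVars <- setdiff(contVars, constVars)

  for (v in useVars) {
    if ("L" %in% classes) addDef("L", v)
    if ("Q" %in% classes) addDef("Q", v)
  }
  if ("P" %in% classes && length(useVars) >= 2) {
    pairs <- utils::combn(useVars, 2)
    for (p in seq_len(ncol(pairs))) addDef("P", pairs[1, p], var2 = pairs[2, p])
  }
  if (any(c("T", "H") %in% classes)) {
    for (v in useVars) {
      ks <- unique(stats::quantile(data[[v]], probs = seq_len(knots) / (knots + 1),
                                   names = FALSE, type = 7))
      hi <- vs$hi[vs$var == v]
      lo <- vs$lo[vs$var == v]
      ks <- ks[ks > lo & ks < hi]       # interior knots only
      for (k in ks) {
        if ("T" %in% classes) addDef("T", v, knot = k)
        if ("H" %in% classes) addDef("H", v, knot = k)
      }
    }
  }
  for (v in intersect(vars, categorical)) {
    for (lev in sort(unique(data[[v]]))) addDef("C", v, level = lev)
  }
  defs <- do.call(rbind, defs)
  if (is.null(defs) || !nrow(defs)) stop("no features could be constructed")
  defs$name <- ifelse(defs$kind == "P", paste0("P(", defs$var, "*", defs$var2, ")"),
               ifelse(defs$kind == "C", paste0("C(", defs$var, "=", defs$level, ")"),
               ifelse(defs$kind %in% c("T", "H"),
                      paste0(defs$kind, "(", defs$var, "@", signif(defs$knot, 6), ")"),
                      paste0(defs$kind, "(", defs$var, ")"))))
  fm <- new("FeatureMatrix", M = .featureValues(data, defs, vs),
            defs = defs, varSummary = vs, classes = classes)
  fm
}

# Evaluate feature definitions on raw data, clamping to training bounds.
.featureValues <- function(data, defs, vs) {
  scaled <- list()
  sc <- function(v) {
    if (!is.null(scaled[[v]])) return(scaled[[v]])
    lo <- vs$lo[vs$var == v]; hi <- vs$hi[vs$var == v]
    s <- if (hi == lo) rep(0, nrow(data)) else
      pmin(pmax((data[[v]] - lo) / (hi - lo), 0), 1)
    scaled[[v]] <<- s
    s
  }
  M <- matrix(0, nrow(data), nrow(defs))
  for (j in seq_len(nrow(defs))) {
    d <- defs[j, ]
    if (!d$var %in% names(data))
      stop(sprintf("feature '%s' references a missing variable '%s'",
                   d$name, d$var))
    M[, j] <- switch(d$kind,
      L = sc(d$var),
      Q = sc(d$var)^2,
      P = {
        if (!d$var2 %in% names(data))
          stop(sprintf("feature '%s' references a missing variable '%s'",
                       d$name, d$var2))
        sc(d$var) * sc(d$var2)
      },
      T = as.numeric(data[[d$var]] > d$knot),
      H = {
        hi <- vs$hi[vs$var == d$var]
        pmin(pmax(0, data[[d$var]] - d$knot) / (hi - d$knot), 1)
      },
      C = as.numeric(data[[d$var]] == d$level))
  }
  if (any(!is.finite(M))) stop("non-finite feature values")
  colnames(M) <- defs$name
  M
}

.expandFromReference <- function(data, reference) {
  if (is(reference, "MaxentModel")) {
    defs <- reference@defs; vs <- reference@varSummary
    classes <- reference@classes
  } else if (is(reference, "FeatureMatrix")) {
    defs <- reference@defs; vs <- reference@varSummary
    classes <- reference@classes
  } else stop("reference must be a FeatureMatrix or MaxentModel")
  missing <- setdiff(unique(c(defs$var, stats::na.omit(defs$var2))), names(data))
  if (length(missing))
    stop(sprintf("data lacks variable(s) required by the model: %s",
                 paste(missing, collapse = ", ")))
  new("FeatureMatrix", M = .featureValues(data, defs, vs), defs = defs,
      varSummary = vs, classes = classes)
}
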