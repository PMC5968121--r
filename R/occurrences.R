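#' @include AllClasses.R
NULL

#' Read and write occurrence records as CSV
#'
#' CSV with columns `x`, `y` (further columns, e.g. source or date, are
#' carried into the provenance notes count but otherwise ignored). Rows
#' whose coordinates do not parse as finite numbers are dropped with a
#' provenance note — the "not geo-referenced" cleaning step.
#'
#' @param path CSV file path.
#' @param occ an [OccurrenceSet-class].
#' @return `readOccurrences()` an [OccurrenceSet-class];
#'   `writeOccurrences()` the path, invisibly.
#' @export
readOccurrences <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop(sprintf("occurrence file %s lacks x,y columns", path))
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  ok <- is.finite(x) & is.finite(y)
  occurrenceSet(x[ok], y[ok],
                provenance = sprintf("read %d records from %s (%d dropped as non-georeferenced)",
                                     nrow(df), basename(path), sum(!ok)))
}

#' @rdname readOccurrences
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(coords(occ)), path, row.names = FALSE)
  invisible(path)
}

#' Clean and spatially rarefy occurrence records
#'
#' Drops exact duplicate coordinates, drops points falling off the grid or
#' on masked cells, then rarefies to one point per occupied grid cell to
#' damp spatial autocorrelation. The first point (in input order) of each
#' cell survives, making the operation deterministic and idempotent.
#'
#' @param occ an [OccurrenceSet-class].
#' @param grid the [RasterGrid-class] or [RasterStack-class] whose cells
#'   define the rarefaction resolution.
#' @return the cleaned [OccurrenceSet-class]; errors if nothing survives.
#' @export
cleanAndRarefy <- function(occ, grid) {
  if (is(grid, "RasterStack")) grid <- grid@layers[[1]]
  pts <- coords(occ)
  n0 <- nrow(pts)
  pts <- pts[!duplicated(pts), , drop = FALSE]
  nDup <- n0 - nrow(pts)
  cell <- cellFromXY(grid, pts)
  onGrid <- !is.na(cell)
  valid <- onGrid
  valid[onGrid] <- as.vector(grid@mask)[cell[onGrid]]
  pts <- pts[valid, , drop = FALSE]
  cell <- cell[valid]
  keep <- !duplicated(cell)
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts))
    stop("no usable occurrences remain after cleaning and rarefaction")
  occurrenceSet(pts, provenance = c(occ@provenance,
    sprintf("cleaned %d -> %d: %d duplicates, %d masked/off-grid, rarefied to one per cell",
            n0, nrow(pts), nDup, sum(!valid))))
}

#' Sample random background points
#'
#' Draws `n` unmasked cell centres uniformly without replacement — the
#' available-environment sample contrasted against presences in
#' presence-only model fitting. If `n` meets or exceeds the number of
#' unmasked cells, every unmasked cell is returned once with a warning.
#'
#' @param stack a [RasterStack-class] (or [RasterGrid-class]).
#' @param n number of background points (default 10000).
#' @param seed integer seed for the draw.
#' @param exclude optional [OccurrenceSet-class]; cells holding these
#'   points are excluded from the candidate pool.
#' @return an [OccurrenceSet-class] of cell centres.
#' @export
sampleBackground <- function(stack, n = 10000, seed = NULL, exclude = NULL) {
  stopifnot(n >= 1)
  ctr <- cellCenters(stack)
  if (!nrow(ctr)) stop("stack is fully masked; no background available")
  if (!is.null(exclude)) {
    ex <- unique(cellFromXY(stack, coords(exclude)))
    keep <- !(attr(ctr, "cell") %in% ex)
    ctr <- ctr[keep, , drop = FALSE]
    if (!nrow(ctr)) stop("no background cells remain after exclusion")
  }
  if (n >= nrow(ctr)) {
    if (n > nrow(ctr))
      warning(sprintf("requested %d background points but only %d unmasked cells; returning all",
                      n, nrow(ctr)))
    pick <- seq_len(nrow(ctr))
  } else {
    pick <- .withSeed(seed, sample.int(nrow(ctr), n))
  }
  occurrenceSet(ctr[pick, , drop = FALSE],
                provenance = sprintf("%d background points", length(pick)))
}

#' Filter collinear predictor variables
#'
#' Greedy elimination of continuous layers by pairwise Pearson
#' correlation: while any retained pair exceeds the cutoff, the
#' lower-priority member of the worst pair is dropped. By default the
#' layer with the higher mean absolute correlation against all other
#' retained layers is dropped first; an explicit `priority` order (earlier
#' = keep) encodes expert preference. Categorical layers pass through
#' unfiltered; constant (zero-variance) layers are dropped with a warning.
#'
#' @param stack a [RasterStack-class].
#' @param cells optional data.frame of layer values over the support on
#'   which correlation is measured (e.g. presence + background cells, via
#'   [extractValues()]); defaults to all unmasked cells.
#' @param cutoff maximum tolerated absolute Pearson correlation
#'   (default 0.85).
#' @param priority optional character vector of layer names, most
#'   preferred first.
#' @return list of class `variableFilter`: `retained` layer names,
#'   `dropped` data.frame (name, partner, r), and the `cutoff`.
#' @export
correlationFilter <- function(stack, cells = NULL, cutoff = 0.85,
                              priority = NULL) {
  catNames <- names(stack@layers)[vapply(stack@layers, isCategorical, logical(1))]
  contNames <- setdiff(names(stack@layers), catNames)
  if (length(contNames) < 2)
    stop("correlation filtering needs at least two continuous layers")
  df <- if (is.null(cells)) cellTable(stack) else cells
  df <- df[, contNames, drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]

  dropped <- data.frame(name = character(0), partner = character(0),
                        r = numeric(0))
  sds <- vapply(df, stats::sd, numeric(1))
  for (nm in contNames[sds == 0]) {
    warning(sprintf("dropping constant layer '%s' (zero variance)", nm))
    dropped <- rbind(dropped, data.frame(name = nm, partner = NA, r = NA))
  }
  retained <- contNames[sds > 0]

  while (length(retained) >= 2) {
    cm <- abs(stats::cor(df[, retained, drop = FALSE]))
    diag(cm) <- 0
    worst <- max(cm)
    if (worst <= cutoff) break
    idx <- which(cm == worst, arr.ind = TRUE)[1, ]
    pair <- retained[idx]
    drop <- if (!is.null(priority) && any(pair %in% priority)) {
      pr <- match(pair, priority)           # NA = unlisted = lowest priority
      pr[is.na(pr)] <- Inf
      pair[which.max(pr)]
    } else {
      pair[which.max(rowMeans(cm)[pair])]   # higher mean |r| dropped first
    }
    keep <- setdiff(pair, drop)
    dropped <- rbind(dropped, data.frame(name = drop, partner = keep, r = worst))
    retained <- setdiff(retained, drop)
  }
  structure(list(retained = c(retained, catNames), dropped = dropped,
                 cutoff = cutoff), class = "variableFilter")
}

#' @export
print.variableFilter <- function(x, ...) {
  cat(sprintf("Variable filter (|r| <= %g): %d retained, %d dropped\n",
              x$cutoff, length(x$retained), nrow(x$dropped)))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Write a correlation-filter report as CSV
#'
#' Columns: name, partner, r, action — one row per layer decision.
#'
#' @param filter a `variableFilter` from [correlationFilter()].
#' @param path output CSV path.
#' @export
writeFilterReport <- function(filter, path) {
  rep1 <- data.frame(name = filter$retained, partner = NA, r = NA,
                     action = "retained")
  rep2 <- if (nrow(filter$dropped))
    cbind(filter$dropped, action = "dropped") else NULL
  utils::write.csv(rbind(rep1, rep2), path, row.names = FALSE)
  invisible(path)
}
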