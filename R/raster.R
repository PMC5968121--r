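#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Cell geometry

#' Cell centres and point-to-cell binning
#'
#' `cellCenters()` returns the planar coordinates of (by default unmasked)
#' cell centres in row-major order. `cellFromXY()` bins points into cells
#' using half-open intervals `[edge, edge + cellSize)` and returns row-major
#' cell indices (`NA` for points off the grid).
#'
#' @param grid a [RasterGrid-class] or [RasterStack-class].
#' @param maskedToo also return centres of masked cells.
#' @param xy two-column matrix of point coordinates.
#' @return `cellCenters()`: matrix with columns x, y and attribute `cell`
#'   (row-major index); `cellFromXY()`: integer vector of cell indices.
#' @export
cellCenters <- function(grid, maskedToo = FALSE) {
  if (is(grid, "RasterStack")) grid <- grid@layers[[1]]
  d <- dim(grid@values); nr <- d[1]; nc <- d[2]
  cs <- grid@cellSize; o <- grid@origin
  row <- rep(seq_len(nr), times = nc)
  col <- rep(seq_len(nc), each = nr)
  keep <- if (maskedToo) rep(TRUE, nr * nc) else as.vector(grid@mask)
  out <- cbind(x = o[1] + (col[keep] - 0.5) * cs,
               y = o[2] + (nr - row[keep] + 0.5) * cs)
  attr(out, "cell") <- which(keep)
  out
}

#' @rdname cellCenters
#' @export
cellFromXY <- function(grid, xy) {
  if (is(grid, "RasterStack")) grid <- grid@layers[[1]]
  d <- dim(grid@values); nr <- d[1]; nc <- d[2]
  cs <- grid@cellSize; o <- grid@origin
  col <- floor((xy[, 1] - o[1]) / cs) + 1
  row <- nr - floor((xy[, 2] - o[2]) / cs)
  bad <- col < 1 | col > nc | row < 1 | row > nr
  idx <- (col - 1) * nr + row
  idx[bad] <- NA_integer_
  as.integer(idx)
}

# ---------------------------------------------------------------------------
# ESRI ASCII Grid I/O

#' Read and write ESRI ASCII Grid rasters
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner/xllcenter, yllcorner/yllcenter, cellsize, NODATA_value)
#' followed by nrows lines of values, northernmost row first. Nodata cells
#' are masked on read and written back as the nodata value, bit-exactly
#' round-tripping mask and values.
#'
#' @param path file path.
#' @param categorical mark the layer categorical (integer class IDs); a
#'   file holding non-integer values is rejected.
#' @param grid a [RasterGrid-class] to write.
#' @param nodata nodata sentinel written for masked cells.
#' @return `readAsciiGrid()` returns a [RasterGrid-class];
#'   `writeAsciiGrid()` returns `path` invisibly.
#' @export
readAsciiGrid <- function(path, categorical = FALSE) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  head <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head), "\\s+")
  keys <- tolower(vapply(kv, `[`, character(1), 1))
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, character(1), 2)))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (any(!need %in% keys) || any(is.na(vals[need])))
    stop(sprintf("not an ESRI ASCII grid (bad header): %s", path))
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  cs <- vals["cellsize"]
  # llcenter variants shift the corner by half a cell
  x0 <- if ("xllcorner" %in% keys) vals["xllcorner"] else
    if ("xllcenter" %in% keys) vals["xllcenter"] - cs / 2 else 0
  y0 <- if ("yllcorner" %in% keys) vals["yllcorner"] else
    if ("yllcenter" %in% keys) vals["yllcenter"] - cs / 2 else 0
  nodata <- if ("nodata_value" %in% keys) vals["nodata_value"] else NA_real_
  nHead <- sum(keys %in% c("ncols", "nrows", "xllcorner", "xllcenter",
                           "yllcorner", "yllcenter", "cellsize",
                           "nodata_value"))
  body <- scan(path, what = double(), skip = nHead, quiet = TRUE)
  if (length(body) != nr * nc)
    stop(sprintf("raster body of %s holds %d values, expected %d x %d",
                 path, length(body), nr, nc))
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  mask <- if (is.na(nodata)) !is.na(m) else !(is.na(m) | m == nodata)
  m[!mask] <- NA_real_
  if (categorical && any(!.isWholeNumber(m[mask])))
    stop(sprintf("categorical raster %s holds non-integer values", path))
  rasterGrid(m, mask = mask, origin = c(unname(x0), unname(y0)),
             cellSize = unname(cs), categorical = categorical)
}

#' @rdname readAsciiGrid
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  stopifnot(is(grid, "RasterGrid"))
  d <- dim(grid@values)
  v <- grid@values
  v[!grid@mask] <- nodata
  hdr <- c(sprintf("ncols %d", d[2]),
           sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", grid@origin[1]),
           sprintf("yllcorner %.10g", grid@origin[2]),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("NODATA_value %.10g", nodata))
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Resampling

#' Resample a stack to a commensurate cell size
#'
#' Aggregation (coarser target) pools square blocks: continuous layers by
#' the mean over valid cells, categorical layers by majority vote (ties to
#' the smallest class ID); a block is valid if any source cell is valid.
#' Disaggregation (finer target) replicates cells. The target cell size
#' must be an integer multiple or divisor of the source resolution.
#'
#' @param stack a [RasterStack-class] (a bare [RasterGrid-class] is also
#'   accepted and returned).
#' @param targetCellSize new cell edge length.
#' @return the resampled stack (or grid).
#' @export
resampleAlign <- function(stack, targetCellSize) {
  single <- is(stack, "RasterGrid")
  if (single) stack <- rasterStack(layer = stack)
  cs <- cellSize(stack)
  ratio <- targetCellSize / cs
  if (.isWholeNumber(ratio)) {
    f <- as.integer(round(ratio))
    out <- lapply(stack@layers, .aggregateGrid, f = f,
                  targetCellSize = targetCellSize)
  } else if (.isWholeNumber(1 / ratio)) {
    f <- as.integer(round(1 / ratio))
    out <- lapply(stack@layers, .disaggregateGrid, f = f,
                  targetCellSize = targetCellSize)
  } else {
    stop(sprintf("target cell size %g is not commensurate with source %g",
                 targetCellSize, cs))
  }
  res <- rasterStack(out)
  if (single) res@layers[[1]] else res
}

.aggregateGrid <- function(grid, f, targetCellSize) {
  if (f == 1L) return(grid)
  d <- dim(grid@values)
  nr <- d[1] %/% f; nc <- d[2] %/% f
  if (nr < 1 || nc < 1) stop("aggregation factor exceeds grid extent")
  vals <- matrix(NA_real_, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    block <- grid@values[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)]
    ok <- !is.na(block)
    if (any(ok)) {
      mask[i, j] <- TRUE
      vals[i, j] <- if (grid@categorical) {
        tab <- table(block[ok])
        as.numeric(names(tab)[which.max(tab)])  # majority, ties -> smaller ID
      } else mean(block[ok])
    }
  }
  # origin keeps the lower-left corner of the covered sub-extent
  y0 <- grid@origin[2] + (d[1] - nr * f) * grid@cellSize
  rasterGrid(vals, mask = mask, origin = c(grid@origin[1], y0),
             cellSize = targetCellSize, categorical = grid@categorical)
}

.disaggregateGrid <- function(grid, f, targetCellSize) {
  if (f == 1L) return(grid)
  idxR <- rep(seq_len(nrow(grid@values)), each = f)
  idxC <- rep(seq_len(ncol(grid@values)), each = f)
  rasterGrid(grid@values[idxR, idxC, drop = FALSE],
             mask = grid@mask[idxR, idxC, drop = FALSE],
             origin = grid@origin, cellSize = targetCellSize,
             categorical = grid@categorical)
}

# ---------------------------------------------------------------------------
# Extraction

#' Predictor values at cells or points
#'
#' `cellTable()` returns the raw predictor values of every unmasked cell
#' (row-major cell order) as a data.frame with a `categorical` attribute
#' naming the categorical layers and a `cell` attribute of cell indices.
#' `extractValues()` does the same at the cells containing a set of
#' points (rows with any point off the grid or on a masked cell are NA).
#'
#' @param stack a [RasterStack-class].
#' @param occ an [OccurrenceSet-class] or two-column coordinate matrix.
#' @return data.frame of predictor values.
#' @export
cellTable <- function(stack) {
  mask <- gridMask(stack)
  keep <- which(as.vector(mask))
  df <- as.data.frame(lapply(stack@layers, function(l) as.vector(l@values)[keep]))
  attr(df, "categorical") <- names(stack@layers)[
    vapply(stack@layers, isCategorical, logical(1))]
  attr(df, "cell") <- keep
  df
}

#' @rdname cellTable
#' @export
extractValues <- function(stack, occ) {
  xy <- if (is(occ, "OccurrenceSet")) occ@points else as.matrix(occ)
  idx <- cellFromXY(stack, xy)
  df <- as.data.frame(lapply(stack@layers, function(l) as.vector(l@values)[idx]))
  attr(df, "categorical") <- names(stack@layers)[
    vapply(stack@layers, isCategorical, logical(1))]
  attr(df, "cell") <- idx
  df
}
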