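#' @include AllGenerics.R
NULL

#' @rdname RasterGrid-class
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname RasterGrid-class
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))

#' @rdname RasterGrid-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname RasterGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname RasterGrid-class
#' @export
setGeneric("isCategorical", function(x) standardGeneric("isCategorical"))

#' @rdname RasterStack-class
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' @rdname RasterStack-class
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname RasterStack-class
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))

#' @rdname OccurrenceSet-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname OccurrenceSet-class
#' @export
setGeneric("nOccurrences", function(x) standardGeneric("nOccurrences"))

#' @rdname MaxentModel-class
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))

#' @rdname MaxentModel-class
#' @export
setGeneric("entropy", function(x) standardGeneric("entropy"))

#' @rdname MaxentModel-class
#' @export
setGeneric("trainingGain", function(x) standardGeneric("trainingGain"))

#' @rdname MaxentModel-class
#' @export
setGeneric("regularizedGain", function(x) standardGeneric("regularizedGain"))

#' @rdname MaxentModel-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' Predict the raw (Gibbs) probability distribution of a fitted model
#'
#' @param object a [MaxentModel-class].
#' @param newdata a [FeatureMatrix-class], a data.frame of raw predictor
#'   values, or a [RasterStack-class].
#' @param ... further arguments passed to methods.
#' @return numeric vector of raw probabilities (relative to the training
#'   background normaliser), or a [RasterGrid-class] when `newdata` is a
#'   stack.
#' @export
setGeneric("predictRaw", function(object, newdata, ...) standardGeneric("predictRaw"))

#' Predict logistic habitat suitability in (0, 1)
#'
#' @inheritParams predictRaw
#' @return numeric vector of logistic suitabilities, or a
#'   [RasterGrid-class] when `newdata` is a stack.
#' @export
setGeneric("predictLogistic", function(object, newdata, ...) standardGeneric("predictLogistic"))
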