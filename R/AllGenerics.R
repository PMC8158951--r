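# Accessor generics. Slots are never touched directly by user code.

#' Accessors for acquisition and basis objects
#'
#' @param object an \code{AcquisitionScheme}, \code{ComponentBasis},
#'   \code{SignalVolume}, \code{FitMaps} or \code{CostSurface} object.
#' @return \code{echoTimes}/\code{bValues}: numeric vectors.
#'   \code{measurementTable}: data.frame with columns \code{te}, \code{b} in
#'   canonical (TE, b) order. \code{nMeasurements}: integer.
#' @name scheme-accessors
#' @aliases echoTimes bValues measurementTable nMeasurements
#' @examples
#' measurementTable(AcquisitionScheme())
NULL

#' @rdname scheme-accessors
#' @export
setGeneric("echoTimes", function(object) standardGeneric("echoTimes"))
#' @rdname scheme-accessors
#' @export
setGeneric("bValues", function(object) standardGeneric("bValues"))
#' @rdname scheme-accessors
#' @export
setGeneric("measurementTable", function(object) standardGeneric("measurementTable"))
#' @rdname scheme-accessors
#' @export
setGeneric("nMeasurements", function(object) standardGeneric("nMeasurements"))

#' @rdname scheme-accessors
#' @export
setMethod("echoTimes", "AcquisitionScheme", function(object) object@echoTimes)
#' @rdname scheme-accessors
#' @export
setMethod("bValues", "AcquisitionScheme", function(object) object@bValues)
#' @rdname scheme-accessors
#' @export
setMethod("measurementTable", "AcquisitionScheme",
          function(object) object@measurements)
#' @rdname scheme-accessors
#' @export
setMethod("nMeasurements", "AcquisitionScheme",
          function(object) nrow(object@measurements))
#' @rdname scheme-accessors
#' @export
setMethod("echoTimes", "SignalVolume", function(object) object@scheme@echoTimes)
#' @rdname scheme-accessors
#' @export
setMethod("bValues", "SignalVolume", function(object) object@scheme@bValues)

#' Component basis accessors
#'
#' @param object a \code{ComponentBasis}.
#' @return \code{adcPair}/\code{t2Pair}: named numeric length-2
#'   (slow, fast), in um^2/ms and ms respectively.
#' @name basis-accessors
#' @aliases adcPair t2Pair
#' @examples
#' t2Pair(ComponentBasis())
NULL

#' @rdname basis-accessors
#' @export
setGeneric("adcPair", function(object) standardGeneric("adcPair"))
#' @rdname basis-accessors
#' @export
setGeneric("t2Pair", function(object) standardGeneric("t2Pair"))
#' @rdname basis-accessors
#' @export
setMethod("adcPair", "ComponentBasis",
          function(object) c(slow = object@adcSlow, fast = object@adcFast))
#' @rdname basis-accessors
#' @export
setMethod("t2Pair", "ComponentBasis",
          function(object) c(slow = object@t2Slow, fast = object@t2Fast))

#' Volume and fit-map accessors
#'
#' @param object a \code{SignalVolume} or \code{FitMaps}.
#' @param name for \code{fitMap}, one of the map names
#'   (\code{"si0"}, \code{"sfSlow"}, \code{"adc"}, \code{"rmse"}).
#' @return \code{volumeData}: the 4D array. \code{boxMask},
#'   \code{backgroundMask}, \code{validMask}: logical 3D arrays.
#'   \code{fitMap}: a numeric 3D array. \code{qcReport}: named list of
#'   exclusion counts. \code{modelName}: character.
#' @name volume-accessors
#' @aliases volumeData boxMask backgroundMask validMask fitMap qcReport
#'   modelName
NULL

#' @rdname volume-accessors
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname volume-accessors
#' @export
setGeneric("boxMask", function(object) standardGeneric("boxMask"))
#' @rdname volume-accessors
#' @export
setGeneric("backgroundMask", function(object) standardGeneric("backgroundMask"))
#' @rdname volume-accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname volume-accessors
#' @export
setGeneric("fitMap", function(object, name) standardGeneric("fitMap"))
#' @rdname volume-accessors
#' @export
setGeneric("qcReport", function(object) standardGeneric("qcReport"))
#' @rdname volume-accessors
#' @export
setGeneric("modelName", function(object) standardGeneric("modelName"))

#' @rdname volume-accessors
#' @export
setMethod("volumeData", "SignalVolume", function(object) object@data)
#' @rdname volume-accessors
#' @export
setMethod("boxMask", "SignalVolume", function(object) object@boxMask)
#' @rdname volume-accessors
#' @export
setMethod("backgroundMask", "SignalVolume",
          function(object) object@backgroundMask)
#' @rdname volume-accessors
#' @export
setMethod("validMask", "FitMaps", function(object) object@valid)
#' @rdname volume-accessors
#' @export
setMethod("fitMap", "FitMaps", function(object, name) {
  if (!name %in% names(object@maps))
    stop("no map named '", name, "'; available: ",
         paste(names(object@maps), collapse = ", "))
  object@maps[[name]]
})
#' @rdname volume-accessors
#' @export
setMethod("qcReport", "FitMaps", function(object) object@qc)
#' @rdname volume-accessors
#' @export
setMethod("modelName", "FitMaps", function(object) object@model)

#' Cost-surface accessors
#'
#' @param object a \code{CostSurface}.
#' @return \code{optimalT2}: named numeric (t2Slow, t2Fast) in ms.
#'   \code{costMatrix}: the cost grid (rows t2Slow, cols t2Fast, NA where
#'   infeasible). \code{t2SlowAxis}/\code{t2FastAxis}: numeric axes.
#'   \code{nVoxels}: pooled voxel count. \code{minimumCost}: the cost at the
#'   optimum. \code{costSurfaceTable}: long-format data.frame
#'   (t2Slow, t2Fast, totalRmse) of the feasible cells.
#' @name costsurface-accessors
#' @aliases optimalT2 costMatrix t2SlowAxis t2FastAxis nVoxels minimumCost
#'   costSurfaceTable
NULL

#' @rdname costsurface-accessors
#' @export
setGeneric("optimalT2", function(object) standardGeneric("optimalT2"))
#' @rdname costsurface-accessors
#' @export
setGeneric("costMatrix", function(object) standardGeneric("costMatrix"))
#' @rdname costsurface-accessors
#' @export
setGeneric("t2SlowAxis", function(object) standardGeneric("t2SlowAxis"))
#' @rdname costsurface-accessors
#' @export
setGeneric("t2FastAxis", function(object) standardGeneric("t2FastAxis"))
#' @rdname costsurface-accessors
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))
#' @rdname costsurface-accessors
#' @export
setGeneric("minimumCost", function(object) standardGeneric("minimumCost"))
#' @rdname costsurface-accessors
#' @export
setGeneric("costSurfaceTable", function(object) standardGeneric("costSurfaceTable"))

#' @rdname costsurface-accessors
#' @export
setMethod("optimalT2", "CostSurface", function(object) object@optimum)
#' @rdname costsurface-accessors
#' @export
setMethod("costMatrix", "CostSurface", function(object) object@totalRmse)
#' @rdname costsurface-accessors
#' @export
setMethod("t2SlowAxis", "CostSurface", function(object) object@t2SlowAxis)
#' @rdname costsurface-accessors
#' @export
setMethod("t2FastAxis", "CostSurface", function(object) object@t2FastAxis)
#' @rdname costsurface-accessors
#' @export
setMethod("nVoxels", "CostSurface", function(object) object@nVoxels)
#' @rdname costsurface-accessors
#' @export
setMethod("minimumCost", "CostSurface", function(object) {
  i <- match(object@optimum[["t2Slow"]], object@t2SlowAxis)
  j <- match(object@optimum[["t2Fast"]], object@t2FastAxis)
  object@totalRmse[i, j]
})
#' @rdname costsurface-accessors
#' @export
setMethod("costSurfaceTable", "CostSurface", function(object) {
  g <- expand.grid(t2Slow = object@t2SlowAxis, t2Fast = object@t2FastAxis,
                   KEEP.OUT.ATTRS = FALSE)
  g$totalRmse <- as.vector(object@totalRmse)
  g[!is.na(g$totalRmse), , drop = FALSE]
})
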