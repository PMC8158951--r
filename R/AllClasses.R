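#' @import methods
NULL

#' Acquisition scheme for combined T2- and diffusion-weighted imaging
#'
#' Describes the measurement design: the cross product of echo times (TE, ms)
#' and diffusion weightings (b, s/mm^2). Each voxel carries one magnitude
#' measurement per (TE, b) combination. The canonical measurement order is the
#' cross product sorted by TE, then b; every signal table and 4D volume in the
#' package uses this order.
#'
#' @slot echoTimes numeric vector of echo times in ms, strictly positive.
#' @slot bValues numeric vector of b-values in s/mm^2, non-negative.
#' @slot measurements data.frame with columns \code{te} and \code{b}, one row
#'   per measurement in canonical order.
#'
#' @examples
#' sch <- AcquisitionScheme()           # the default 2x2 design
#' measurementTable(sch)
#' @export
setClass("AcquisitionScheme",
  slots = c(
    echoTimes = "numeric",
    bValues = "numeric",
    measurements = "data.frame"
  )
)

setValidity("AcquisitionScheme", function(object) {
  msg <- character()
  if (length(object@echoTimes) < 1 || any(object@echoTimes <= 0))
    msg <- c(msg, "all echo times must be > 0 ms")
  if (length(object@bValues) < 1 || any(object@bValues < 0))
    msg <- c(msg, "all b-values must be >= 0 s/mm^2")
  m <- object@measurements
  if (!identical(colnames(m), c("te", "b")))
    msg <- c(msg, "measurements must have columns te, b")
  else {
    if (nrow(m) != length(object@echoTimes) * length(object@bValues))
      msg <- c(msg, "measurements must be the full TE x b cross product")
    ord <- order(m$te, m$b)
    if (!identical(ord, seq_len(nrow(m))))
      msg <- c(msg, "measurements must be sorted by (te, b)")
  }
  if (length(msg)) msg else TRUE
})

#' @param echoTimes numeric vector of echo times in ms.
#' @param bValues numeric vector of b-values in s/mm^2.
#' @return \code{AcquisitionScheme()} returns an AcquisitionScheme object.
#' @rdname AcquisitionScheme-class
#' @export
AcquisitionScheme <- function(echoTimes = c(55, 73), bValues = c(50, 700)) {
  echoTimes <- sort(as.numeric(echoTimes))
  bValues <- sort(as.numeric(bValues))
  grid <- expand.grid(b = bValues, te = echoTimes,
                      KEEP.OUT.ATTRS = FALSE)[, c("te", "b")]
  rownames(grid) <- NULL
  new("AcquisitionScheme", echoTimes = echoTimes, bValues = bValues,
      measurements = grid)
}

#' Fixed slow/fast component basis
#'
#' The two-component model assigns each voxel's signal to a slow compartment
#' (low diffusivity, short T2; intracellular/epithelial water) and a fast
#' compartment (high diffusivity, long T2; luminal/extracellular water).
#' The per-component apparent diffusion coefficients are fixed population
#' values (defaults 0.3 and 2.6 um^2/ms); the per-component T2 values are
#' population-calibrated by pooled grid search (see \code{\link{calibrateT2}};
#' defaults 45 and 180 ms).
#'
#' @slot adcSlow,adcFast diffusivities in um^2/ms, 0 < adcSlow < adcFast.
#' @slot t2Slow,t2Fast relaxation times in ms, 0 < t2Slow < t2Fast.
#'
#' @examples
#' ComponentBasis()
#' ComponentBasis(t2Slow = 50, t2Fast = 200)
#' @export
setClass("ComponentBasis",
  slots = c(adcSlow = "numeric", adcFast = "numeric",
            t2Slow = "numeric", t2Fast = "numeric")
)

setValidity("ComponentBasis", function(object) {
  msg <- character()
  for (s in c("adcSlow", "adcFast", "t2Slow", "t2Fast"))
    if (length(slot(object, s)) != 1 || !is.finite(slot(object, s)))
      msg <- c(msg, sprintf("%s must be a finite scalar", s))
  if (!length(msg)) {
    if (!(object@adcSlow > 0 && object@adcSlow < object@adcFast))
      msg <- c(msg, "require 0 < adcSlow < adcFast (um^2/ms)")
    if (!(object@t2Slow > 0 && object@t2Slow < object@t2Fast))
      msg <- c(msg, "require 0 < t2Slow < t2Fast (ms)")
  }
  if (length(msg)) msg else TRUE
})

#' @param adcSlow,adcFast diffusivities in um^2/ms.
#' @param t2Slow,t2Fast relaxation times in ms.
#' @return \code{ComponentBasis()} returns a ComponentBasis object.
#' @rdname ComponentBasis-class
#' @export
ComponentBasis <- function(adcSlow = 0.3, adcFast = 2.6,
                           t2Slow = 45, t2Fast = 180) {
  new("ComponentBasis", adcSlow = as.numeric(adcSlow),
      adcFast = as.numeric(adcFast), t2Slow = as.numeric(t2Slow),
      t2Fast = as.numeric(t2Fast))
}

#' 4D magnitude volume with acquisition metadata and masks
#'
#' Holds the co-registered trace-weighted magnitude data as a 4D array
#' (x, y, z, measurement), the acquisition scheme describing the measurement
#' axis, the voxel size in mm, and two 3D logical masks: \code{boxMask}, the
#' box-shaped region covering the organ of interest, and
#' \code{backgroundMask}, an air-only region used to estimate the noise floor.
#'
#' @slot data numeric 4D array, non-negative magnitudes.
#' @slot scheme an \code{\link{AcquisitionScheme-class}} object.
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot boxMask,backgroundMask logical 3D arrays on the data lattice;
#'   disjoint.
#' @export
setClass("SignalVolume",
  slots = c(
    data = "array",
    scheme = "AcquisitionScheme",
    voxelSize = "numeric",
    boxMask = "array",
    backgroundMask = "array"
  )
)

setValidity("SignalVolume", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4)
    return("data must be a 4D array (x, y, z, measurement)")
  if (d[4] != nrow(object@scheme@measurements))
    msg <- c(msg, "4th dimension of data must match the scheme's measurement count")
  for (s in c("boxMask", "backgroundMask")) {
    m <- slot(object, s)
    if (!is.logical(m) || !identical(dim(m), d[1:3]))
      msg <- c(msg, sprintf("%s must be a logical array with the data's spatial shape", s))
  }
  if (!length(msg) && any(object@boxMask & object@backgroundMask))
    msg <- c(msg, "boxMask and backgroundMask must be disjoint")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (any(!is.finite(object@data)) || any(object@data < 0))
    msg <- c(msg, "data must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' @param data numeric 4D array (x, y, z, measurement).
#' @param scheme an AcquisitionScheme.
#' @param voxelSize numeric length-3, mm.
#' @param boxMask,backgroundMask logical 3D arrays.
#' @return \code{SignalVolume()} returns a SignalVolume object.
#' @rdname SignalVolume-class
#' @export
SignalVolume <- function(data, scheme = AcquisitionScheme(),
                         voxelSize = c(2, 2, 3),
                         boxMask = NULL, backgroundMask = NULL) {
  d <- dim(data)
  if (is.null(boxMask)) boxMask <- array(TRUE, d[1:3])
  if (is.null(backgroundMask)) backgroundMask <- array(FALSE, d[1:3])
  new("SignalVolume", data = data, scheme = scheme,
      voxelSize = as.numeric(voxelSize),
      boxMask = boxMask, backgroundMask = backgroundMask)
}

#' Per-voxel parameter maps from a model fit
#'
#' Result container for \code{\link{fitVolume}}: one 3D map per fitted
#' parameter, a validity mask, and a QC report of the exclusion rules.
#' Excluded or unfitted voxels hold \code{NA} in every map (never zero:
#' zero is a legal signal fraction).
#'
#' @slot model one of \code{"twoComponent"}, \code{"biExponential"},
#'   \code{"mono"}.
#' @slot maps named list of numeric 3D arrays: always \code{si0} and
#'   \code{rmse}; \code{sfSlow} for the two-component and bi-exponential
#'   models, \code{adc} (um^2/ms) for the mono-exponential model.
#' @slot valid logical 3D array; TRUE where a fit exists.
#' @slot qc named list of exclusion counts (see
#'   \code{\link{buildExclusionMask}}).
#' @export
setClass("FitMaps",
  slots = c(model = "character", maps = "list", valid = "array", qc = "list")
)

setValidity("FitMaps", function(object) {
  msg <- character()
  if (!object@model %in% c("twoComponent", "biExponential", "mono"))
    msg <- c(msg, "unknown model")
  d <- dim(object@valid)
  if (length(d) != 3 || !is.logical(object@valid))
    msg <- c(msg, "valid must be a logical 3D array")
  for (nm in names(object@maps)) {
    if (!identical(dim(object@maps[[nm]]), d))
      msg <- c(msg, sprintf("map '%s' shape differs from valid mask", nm))
  }
  if (!length(msg) && "sfSlow" %in% names(object@maps)) {
    sf <- object@maps$sfSlow[object@valid]
    if (length(sf) && (any(!is.finite(sf)) || any(sf < -1e-12) || any(sf > 1 + 1e-12)))
      msg <- c(msg, "valid voxels must have sfSlow in [0, 1]")
  }
  if (!length(msg)) {
    for (nm in names(object@maps)) {
      v <- object@maps[[nm]][!object@valid]
      if (length(v) && any(!is.na(v)))
        msg <- c(msg, sprintf("invalid voxels must be NA in map '%s'", nm))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Pooled cost surface from the T2 grid search
#'
#' Stores the pooled fit cost (sum over voxels of per-voxel RMSE) for every
#' candidate (t2Slow, t2Fast) pair, the argmin, and the pooled voxel count.
#' Only cells with t2Slow < t2Fast are populated; the rest are \code{NA}.
#'
#' @slot t2SlowAxis,t2FastAxis candidate T2 values in ms.
#' @slot totalRmse numeric matrix, rows = t2SlowAxis, cols = t2FastAxis.
#' @slot optimum named numeric length-2: the (t2Slow, t2Fast) at the grid
#'   minimum.
#' @slot nVoxels integer, pooled voxel count.
#' @export
setClass("CostSurface",
  slots = c(t2SlowAxis = "numeric", t2FastAxis = "numeric",
            totalRmse = "matrix", optimum = "numeric", nVoxels = "integer")
)

setValidity("CostSurface", function(object) {
  msg <- character()
  if (!identical(dim(object@totalRmse),
                 c(length(object@t2SlowAxis), length(object@t2FastAxis))))
    msg <- c(msg, "totalRmse must be |t2SlowAxis| x |t2FastAxis|")
  else {
    feas <- outer(object@t2SlowAxis, object@t2FastAxis, `<`)
    vals <- object@totalRmse[feas]
    if (any(is.na(vals)) || any(vals < 0))
      msg <- c(msg, "feasible cells must hold non-negative costs")
    if (any(!is.na(object@totalRmse[!feas])))
      msg <- c(msg, "cells with t2Slow >= t2Fast must be NA")
    opt <- object@optimum
    if (length(opt) != 2 || !identical(names(opt), c("t2Slow", "t2Fast")))
      msg <- c(msg, "optimum must be named c(t2Slow=, t2Fast=)")
    else if (!length(msg)) {
      i <- match(opt[["t2Slow"]], object@t2SlowAxis)
      j <- match(opt[["t2Fast"]], object@t2FastAxis)
      if (is.na(i) || is.na(j) ||
          object@totalRmse[i, j] > min(vals) + 1e-9 * max(1, min(vals)))
        msg <- c(msg, "optimum must be the argmin of the stored grid")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AcquisitionScheme", function(object) {
  cat("AcquisitionScheme:",
      length(object@echoTimes), "TE x", length(object@bValues), "b =",
      nrow(object@measurements), "measurements\n")
  cat("  TE (ms):", paste(object@echoTimes, collapse = ", "), "\n")
  cat("  b (s/mm^2):", paste(object@bValues, collapse = ", "), "\n")
})

setMethod("show", "ComponentBasis", function(object) {
  cat("ComponentBasis (slow | fast):\n")
  cat(sprintf("  ADC (um^2/ms): %.3g | %.3g\n", object@adcSlow, object@adcFast))
  cat(sprintf("  T2 (ms):       %.4g | %.4g\n", object@t2Slow, object@t2Fast))
})

setMethod("show", "SignalVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("SignalVolume: %d x %d x %d voxels, %d measurements\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel size (mm): %s\n",
              paste(object@voxelSize, collapse = " x ")))
  cat(sprintf("  box voxels: %d; background voxels: %d\n",
              sum(object@boxMask), sum(object@backgroundMask)))
})

setMethod("show", "FitMaps", function(object) {
  cat(sprintf("FitMaps ('%s' model): maps %s\n", object@model,
              paste(names(object@maps), collapse = ", ")))
  cat(sprintf("  valid voxels: %d\n", sum(object@valid)))
  if (length(object@qc))
    cat(sprintf("  excluded fraction in box: %.3f\n",
                object@qc$excludedFraction))
})

setMethod("show", "CostSurface", function(object) {
  cat(sprintf("CostSurface: %d x %d grid, pooled over %d voxels\n",
              length(object@t2SlowAxis), length(object@t2FastAxis),
              object@nVoxels))
  cat(sprintf("  optimum: t2Slow = %g ms, t2Fast = %g ms (cost %.6g)\n",
              object@optimum[["t2Slow"]], object@optimum[["t2Fast"]],
              minimumCost(object)))
})
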