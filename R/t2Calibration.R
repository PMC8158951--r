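# Population calibration of the component T2 pair. With the T2 pair held
# fixed, each voxel's fit reduces to the 2-parameter linear problem, so the
# pooled cost over a candidate grid is cheap to evaluate exactly.

#' Default T2 candidate grid
#'
#' Brackets the plausible tissue range: short-T2 (epithelial/cellular)
#' candidates 20-100 ms in 5 ms steps, long-T2 (stromal/luminal) candidates
#' 100-400 ms in 10 ms steps.
#'
#' @return list with numeric vectors \code{t2Slow} and \code{t2Fast} (ms).
#' @examples
#' str(defaultT2Grid())
#' @export
defaultT2Grid <- function() {
  list(t2Slow = seq(20, 100, by = 5), t2Fast = seq(100, 400, by = 10))
}

#' Pooled fit cost at a fixed T2 pair
#'
#' The global cost is the sum over all pooled voxels of the per-voxel
#' root-mean-square residual of the two-component fit with the candidate
#' T2 pair held fixed (so only two parameters are fitted per voxel).
#'
#' @param signals numeric matrix of pooled voxel signals, one row per
#'   measurement (canonical order), one column per voxel. Every voxel is
#'   expected to have passed \code{\link{buildExclusionMask}}.
#' @param scheme an AcquisitionScheme.
#' @param basis a ComponentBasis carrying the candidate T2 pair (and the
#'   fixed ADC pair).
#' @param perVoxelNormalize if TRUE, each voxel's RMSE is divided by its
#'   mean signal before summing, so bright voxels do not dominate the pool.
#'   Default FALSE: raw-residual RMSE, matching the cost definition used for
#'   calibration.
#' @return scalar total cost (scanner units, or dimensionless when
#'   normalized).
#' @examples
#' sch <- AcquisitionScheme(); bas <- ComponentBasis()
#' S <- twoComponentSignal(c(100, 80), c(0.7, 0.3), sch, bas)
#' gridCost(S, sch, bas)   # 0: generated at the probe pair
#' @export
gridCost <- function(signals, scheme, basis, perVoxelNormalize = FALSE) {
  signals <- as.matrix(signals)
  if (ncol(signals) == 0) stop("empty voxel pool")
  stopifnot(nrow(signals) == nMeasurements(scheme))
  A <- attenuationBasis(scheme, basis)
  f <- .fitTwoComponentMatrix(signals, A)
  r <- f$rmse
  if (perVoxelNormalize) r <- r / colMeans(signals)
  sum(r)
}

#' Grid search for the population T2 pair
#'
#' Evaluates \code{\link{gridCost}} on every feasible grid cell
#' (t2Slow < t2Fast) and returns the full surface with its argmin. The
#' search is deterministic; exact cost ties are broken toward the smallest
#' t2Slow, then the smallest t2Fast.
#'
#' @inheritParams gridCost
#' @param adcPair numeric length-2 (slow, fast) diffusivities in um^2/ms.
#' @param t2SlowGrid,t2FastGrid candidate values in ms; defaults from
#'   \code{\link{defaultT2Grid}}.
#' @return a \code{\link{CostSurface-class}} object.
#' @examples
#' sch <- AcquisitionScheme(); bas <- ComponentBasis()  # truth (45, 180)
#' S <- twoComponentSignal(runif(50, 50, 150), runif(50), sch, bas)
#' optimalT2(calibrateT2(S, sch))
#' @export
calibrateT2 <- function(signals, scheme, adcPair = c(0.3, 2.6),
                        t2SlowGrid = defaultT2Grid()$t2Slow,
                        t2FastGrid = defaultT2Grid()$t2Fast,
                        perVoxelNormalize = FALSE) {
  signals <- as.matrix(signals)
  if (ncol(signals) == 0) stop("empty voxel pool")
  cost <- matrix(NA_real_, length(t2SlowGrid), length(t2FastGrid))
  for (j in seq_along(t2FastGrid)) {
    for (i in seq_along(t2SlowGrid)) {
      if (t2SlowGrid[i] >= t2FastGrid[j]) next
      bas <- ComponentBasis(adcPair[1], adcPair[2],
                            t2SlowGrid[i], t2FastGrid[j])
      cost[i, j] <- gridCost(signals, scheme, bas, perVoxelNormalize)
    }
  }
  .costSurface(t2SlowGrid, t2FastGrid, cost, ncol(signals))
}

# argmin with deterministic tie-break: smallest t2Slow, then smallest t2Fast
.costSurface <- function(t2SlowGrid, t2FastGrid, cost, nVox) {
  mn <- min(cost, na.rm = TRUE)
  hits <- which(cost == mn, arr.ind = TRUE)
  hits <- hits[order(t2SlowGrid[hits[, 1]], t2FastGrid[hits[, 2]]), ,
               drop = FALSE]
  opt <- c(t2Slow = t2SlowGrid[hits[1, 1]], t2Fast = t2FastGrid[hits[1, 2]])
  new("CostSurface", t2SlowAxis = as.numeric(t2SlowGrid),
      t2FastAxis = as.numeric(t2FastGrid), totalRmse = cost,
      optimum = opt, nVoxels = as.integer(nVox))
}

#' Scale a cost surface so its maximum equals 1
#'
#' Divides every populated cell by the maximum populated cost, the
#' convention used to display the calibration surface. Order-preserving:
#' the argmin is unchanged; applying it twice is a no-op.
#'
#' @param surface a \code{\link{CostSurface-class}} object.
#' @return a CostSurface with max cell value exactly 1.
#' @export
normalizeCostSurface <- function(surface) {
  stopifnot(is(surface, "CostSurface"))
  mx <- max(surface@totalRmse, na.rm = TRUE)
  if (mx > 0) surface@totalRmse <- surface@totalRmse / mx
  validObject(surface)
  surface
}
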