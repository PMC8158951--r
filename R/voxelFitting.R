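# Per-voxel estimation for the three models plus the pre-fit exclusion rules.
#
# The two-component model with fixed decays is linear in
# (a, b) = (si0*sfSlow, si0*sfFast), so the voxel fit is a 2-column
# non-negative linear least-squares problem: convex, global optimum, no
# initialization. The 2-variable NNLS is solved in closed form: if the
# unconstrained normal-equation solution is feasible it is the optimum;
# otherwise the optimum sits on one of the two single-component boundaries.

# S: nMeas x nVox signal matrix, A: nMeas x 2 attenuation basis.
# Returns list(si0, sfSlow, rmse) vectors (NA where degenerate).
.fitTwoComponentMatrix <- function(S, A) {
  nMeas <- nrow(A)
  AtA <- crossprod(A)
  AtS <- crossprod(A, S)                      # 2 x nVox
  SS <- colSums(S * S)
  X <- solve(AtA, AtS)                        # unconstrained solution
  bad <- X[1, ] < 0 | X[2, ] < 0
  if (any(bad)) {
    # boundary candidates: pure slow (x2 = 0) and pure fast (x1 = 0)
    x1o <- pmax(0, AtS[1, bad] / AtA[1, 1])
    x2o <- pmax(0, AtS[2, bad] / AtA[2, 2])
    r1 <- SS[bad] - 2 * x1o * AtS[1, bad] + x1o^2 * AtA[1, 1]
    r2 <- SS[bad] - 2 * x2o * AtS[2, bad] + x2o^2 * AtA[2, 2]
    useSlow <- r1 <= r2
    X[1, bad] <- ifelse(useSlow, x1o, 0)
    X[2, bad] <- ifelse(useSlow, 0, x2o)
  }
  si0 <- unname(X[1, ] + X[2, ])
  sfSlow <- unname(ifelse(si0 > 0, X[1, ] / si0, NA_real_))
  res2 <- colSums((A %*% X - S)^2)     # direct residual: no cancellation
  rmse <- unname(sqrt(res2 / nMeas))
  list(si0 = si0, sfSlow = sfSlow, rmse = rmse)
}

#' Pre-fit voxel exclusion: noise floor and negative apparent decays
#'
#' Implements the two exclusion rules applied before any model fitting:
#' \itemize{
#'   \item \emph{Noise floor}: the noise floor is the average signal
#'     intensity of the background (air) voxels across all measurements; a
#'     voxel is excluded if any of its measurements is equal to or below
#'     three times the noise floor.
#'   \item \emph{Negative apparent decay}: a voxel is excluded if any
#'     apparent decay rate is negative, i.e. the signal rises with b at a
#'     fixed TE (apparent ADC < 0) or rises with TE at a fixed b (apparent
#'     T2 < 0). Every adjacent pair along each axis is tested.
#' }
#' Only voxels inside the box mask are considered for keeping.
#'
#' @param volume a \code{\link{SignalVolume-class}} object with a non-empty
#'   background mask.
#' @return list with \code{keep} (logical 3D array, TRUE = fit this voxel;
#'   always FALSE outside the box) and \code{qc}, a named list:
#'   \code{noiseFloor}, \code{nBox}, \code{nBackground},
#'   \code{nBelowNoiseFloor}, \code{nNegativeAdc}, \code{nNegativeT2},
#'   \code{nExcluded}, \code{excludedFraction}.
#' @examples
#' ph <- buildPhantom(phantomSpec(), type = "cancer_pz", seed = 1)
#' vol <- simulateSignals(ph, sigma = 2.5, seed = 2)
#' ex <- buildExclusionMask(vol)
#' ex$qc$excludedFraction
#' @export
buildExclusionMask <- function(volume) {
  stopifnot(is(volume, "SignalVolume"))
  bg <- backgroundMask(volume)
  if (!any(bg))
    stop("background mask is empty: a background (air) region is required ",
         "to estimate the noise floor")
  dat <- volumeData(volume)
  d <- dim(dat)
  nVox <- prod(d[1:3])
  S4 <- matrix(dat, nrow = nVox, ncol = d[4])   # voxel x measurement
  noiseFloor <- mean(S4[as.vector(bg), , drop = FALSE])
  box <- as.vector(boxMask(volume))
  Sb <- S4[box, , drop = FALSE]

  belowFloor <- rowSums(Sb <= 3 * noiseFloor) > 0

  m <- measurementTable(volume@scheme)
  negAdc <- rep(FALSE, nrow(Sb))
  negT2 <- rep(FALSE, nrow(Sb))
  for (te in unique(m$te)) {
    idx <- which(m$te == te)
    idx <- idx[order(m$b[idx])]
    for (k in seq_len(length(idx) - 1))
      # apparent ADC = ln(S_b1/S_b2)/((b2-b1)*1e-3) < 0  <=>  S_b2 > S_b1
      negAdc <- negAdc | (Sb[, idx[k + 1]] > Sb[, idx[k]])
  }
  for (b in unique(m$b)) {
    idx <- which(m$b == b)
    idx <- idx[order(m$te[idx])]
    for (k in seq_len(length(idx) - 1))
      # apparent T2 = (TE2-TE1)/ln(S_TE1/S_TE2) < 0  <=>  S_TE2 > S_TE1
      negT2 <- negT2 | (Sb[, idx[k + 1]] > Sb[, idx[k]])
  }

  excluded <- belowFloor | negAdc | negT2
  keep <- array(FALSE, d[1:3])
  keep[box] <- !excluded
  list(
    keep = keep,
    qc = list(
      noiseFloor = noiseFloor,
      nBox = sum(box),
      nBackground = sum(bg),
      nBelowNoiseFloor = sum(belowFloor),
      nNegativeAdc = sum(negAdc),
      nNegativeT2 = sum(negT2),
      nExcluded = sum(excluded),
      excludedFraction = sum(excluded) / max(1L, sum(box))
    )
  )
}

#' Fit the two-component model to one voxel
#'
#' With both component ADCs and T2s fixed, only two parameters remain per
#' voxel. The fit solves the non-negative linear least-squares problem in
#' (si0*sfSlow, si0*sfFast) against \code{\link{attenuationBasis}}; the
#' problem is convex with independent basis columns, so the minimizer is
#' unique and needs no initialization. Non-negativity of both components
#' constrains sfSlow to [0, 1].
#'
#' @param signal numeric vector, one magnitude per measurement in the
#'   scheme's canonical order.
#' @param scheme an AcquisitionScheme.
#' @param basis a ComponentBasis.
#' @return list with \code{si0} (= sum of components), \code{sfSlow},
#'   \code{rmse} (root-mean-square residual over the measurements) and
#'   \code{valid} (FALSE for all-zero or non-finite input).
#' @examples
#' sch <- AcquisitionScheme(); bas <- ComponentBasis()
#' s <- twoComponentSignal(100, 0.67, sch, bas)
#' fitTwoComponentVoxel(s, sch, bas)
#' @export
fitTwoComponentVoxel <- function(signal, scheme, basis) {
  stopifnot(length(signal) == nMeasurements(scheme))
  if (any(!is.finite(signal)) || all(signal == 0))
    return(list(si0 = NA_real_, sfSlow = NA_real_, rmse = NA_real_,
                valid = FALSE))
  A <- attenuationBasis(scheme, basis)
  f <- .fitTwoComponentMatrix(matrix(signal, ncol = 1), A)
  list(si0 = f$si0, sfSlow = f$sfSlow, rmse = f$rmse,
       valid = is.finite(f$sfSlow))
}

#' Fit the bi-exponential ADC model to two b-value measurements
#'
#' At a single TE the two-pool diffusion model has an exact solution for two
#' measurements: the signal ratio is linear in sfSlow. The fraction is then
#' clipped to [0, 1] and si0 refit by least squares under the clip.
#'
#' @param sB1,sB2 magnitudes at \code{b1} and \code{b2} (b1 < b2).
#' @param b1,b2 b-values in s/mm^2.
#' @param basis a ComponentBasis; only its ADC pair is used.
#' @return list with \code{si0}, \code{sfSlow}, \code{rmse} and \code{valid}
#'   (FALSE for non-positive input or rising signal, which clips to the
#'   boundary and is flagged for exclusion).
#' @examples
#' s <- biExponentialSignal(1, 0.42, c(50, 700), ComponentBasis())
#' fitBiExponentialVoxel(s[1], s[2], 50, 700, ComponentBasis())
#' @export
fitBiExponentialVoxel <- function(sB1, sB2, b1, b2, basis) {
  stopifnot(b1 < b2)
  if (!is.finite(sB1) || !is.finite(sB2) || sB1 <= 0 || sB2 < 0)
    return(list(si0 = NA_real_, sfSlow = NA_real_, rmse = NA_real_,
                valid = FALSE))
  adc <- adcPair(basis)
  e1s <- exp(-b1 * adc[["slow"]] * .B_ADC_SCALE)
  e1f <- exp(-b1 * adc[["fast"]] * .B_ADC_SCALE)
  e2s <- exp(-b2 * adc[["slow"]] * .B_ADC_SCALE)
  e2f <- exp(-b2 * adc[["fast"]] * .B_ADC_SCALE)
  sf <- (sB1 * e2f - sB2 * e1f) / (sB2 * (e1s - e1f) - sB1 * (e2s - e2f))
  clipped <- !is.finite(sf) || sf < 0 || sf > 1
  sf <- min(1, max(0, if (is.finite(sf)) sf else 0))
  g <- c(sf * e1s + (1 - sf) * e1f, sf * e2s + (1 - sf) * e2f)
  s <- c(sB1, sB2)
  si0 <- sum(g * s) / sum(g * g)
  rmse <- sqrt(mean((si0 * g - s)^2))
  list(si0 = si0, sfSlow = sf, rmse = rmse, valid = !clipped)
}

#' Fit the mono-exponential ADC model to two b-value measurements
#'
#' Closed form, exact for two points:
#' \code{adc = ln(sB1/sB2) / ((b2 - b1) * 1e-3)} in um^2/ms and
#' \code{si0 = sB1 * exp(b1 * adc * 1e-3)}. A negative ADC (rising signal)
#' is returned as-is but flagged, feeding the exclusion rule.
#'
#' @inheritParams fitBiExponentialVoxel
#' @return list with \code{si0}, \code{adc} (um^2/ms) and \code{valid}
#'   (FALSE for non-positive signals or negative ADC).
#' @examples
#' fitMonoAdcVoxel(100, 52.205, 50, 700)   # adc = 1.000 um^2/ms
#' @export
fitMonoAdcVoxel <- function(sB1, sB2, b1, b2) {
  stopifnot(b1 < b2)
  if (!is.finite(sB1) || !is.finite(sB2) || sB1 <= 0 || sB2 <= 0)
    return(list(si0 = NA_real_, adc = NA_real_, valid = FALSE))
  adc <- log(sB1 / sB2) / ((b2 - b1) * .B_ADC_SCALE)
  si0 <- sB1 * exp(b1 * adc * .B_ADC_SCALE)
  list(si0 = si0, adc = adc, valid = adc >= 0)
}

#' Fit a model over every kept voxel of a volume
#'
#' Applies \code{\link{buildExclusionMask}} (unless a precomputed exclusion
#' is supplied), then fits the requested model to every kept voxel inside
#' the box mask. The bi-exponential and mono-exponential models use the two
#' b-value measurements at the longest TE of the scheme. Excluded voxels
#' carry \code{NA} in every output map.
#'
#' @param volume a \code{\link{SignalVolume-class}} object.
#' @param model \code{"twoComponent"}, \code{"biExponential"} or
#'   \code{"mono"}.
#' @param basis a ComponentBasis (for \code{"mono"} only used to locate the
#'   TE = max measurements; may be the default).
#' @param exclusion optional result of \code{\link{buildExclusionMask}} on
#'   the same volume, to avoid recomputation across models.
#' @return a \code{\link{FitMaps-class}} object.
#' @examples
#' ph <- buildPhantom(phantomSpec(), type = "cancer_pz", seed = 1)
#' vol <- simulateSignals(ph, sigma = 0)
#' fm <- fitVolume(vol, "twoComponent", ComponentBasis())
#' range(fitMap(fm, "sfSlow"), na.rm = TRUE)
#' @export
fitVolume <- function(volume,
                      model = c("twoComponent", "biExponential", "mono"),
                      basis = ComponentBasis(), exclusion = NULL) {
  model <- match.arg(model)
  stopifnot(is(volume, "SignalVolume"))
  if (is.null(exclusion)) exclusion <- buildExclusionMask(volume)
  keep <- exclusion$keep
  dat <- volumeData(volume)
  d <- dim(dat)
  S4 <- matrix(dat, nrow = prod(d[1:3]), ncol = d[4])
  kIdx <- which(as.vector(keep))
  if (!length(kIdx))
    stop("no voxels remain after exclusion")
  S <- t(S4[kIdx, , drop = FALSE])               # nMeas x nKept

  blank <- function() array(NA_real_, d[1:3])
  maps <- list()
  m <- measurementTable(volume@scheme)

  if (model == "twoComponent") {
    A <- attenuationBasis(volume@scheme, basis)
    f <- .fitTwoComponentMatrix(S, A)
    ok <- is.finite(f$sfSlow)
    maps$si0 <- blank(); maps$sfSlow <- blank(); maps$rmse <- blank()
    maps$si0[kIdx[ok]] <- f$si0[ok]
    maps$sfSlow[kIdx[ok]] <- f$sfSlow[ok]
    maps$rmse[kIdx[ok]] <- f$rmse[ok]
  } else {
    teFit <- max(m$te)
    idx <- which(m$te == teFit)
    idx <- idx[order(m$b[idx])]
    if (length(idx) != 2)
      stop("bi-/mono-exponential fitting requires exactly two b-values at ",
           "the longest TE")
    b1 <- m$b[idx[1]]; b2 <- m$b[idx[2]]
    s1 <- S[idx[1], ]; s2 <- S[idx[2], ]
    if (model == "mono") {
      adc <- log(s1 / s2) / ((b2 - b1) * .B_ADC_SCALE)
      si0 <- s1 * exp(b1 * adc * .B_ADC_SCALE)
      ok <- is.finite(adc)
      maps$si0 <- blank(); maps$adc <- blank(); maps$rmse <- blank()
      maps$si0[kIdx[ok]] <- si0[ok]
      maps$adc[kIdx[ok]] <- adc[ok]
      maps$rmse[kIdx[ok]] <- 0      # exact two-point fit
    } else {
      adc <- adcPair(basis)
      e1s <- exp(-b1 * adc[["slow"]] * .B_ADC_SCALE)
      e1f <- exp(-b1 * adc[["fast"]] * .B_ADC_SCALE)
      e2s <- exp(-b2 * adc[["slow"]] * .B_ADC_SCALE)
      e2f <- exp(-b2 * adc[["fast"]] * .B_ADC_SCALE)
      sf <- (s1 * e2f - s2 * e1f) / (s2 * (e1s - e1f) - s1 * (e2s - e2f))
      sf <- pmin(1, pmax(0, ifelse(is.finite(sf), sf, 0)))
      g1 <- sf * e1s + (1 - sf) * e1f
      g2 <- sf * e2s + (1 - sf) * e2f
      si0 <- (g1 * s1 + g2 * s2) / (g1^2 + g2^2)
      rmse <- sqrt(((si0 * g1 - s1)^2 + (si0 * g2 - s2)^2) / 2)
      ok <- is.finite(sf)
      maps$si0 <- blank(); maps$sfSlow <- blank(); maps$rmse <- blank()
      maps$si0[kIdx[ok]] <- si0[ok]
      maps$sfSlow[kIdx[ok]] <- sf[ok]
      maps$rmse[kIdx[ok]] <- rmse[ok]
    }
  }

  valid <- array(FALSE, d[1:3])
  valid[kIdx[ok]] <- TRUE
  new("FitMaps", model = model, maps = maps, valid = valid,
      qc = exclusion$qc)
}
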