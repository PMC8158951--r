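# Forward signal equations. All three models share one unit convention:
# b [s/mm^2] * ADC [um^2/ms] * 1e-3 is dimensionless; the 1e-3 conversion
# lives here and nowhere else.

.B_ADC_SCALE <- 1e-3

#' Slow/fast attenuation basis for an acquisition scheme
#'
#' Evaluates, for every measurement (TE, b) of the scheme, the attenuation of
#' each component: \code{exp(-TE / T2_c) * exp(-b * ADC_c * 1e-3)} for
#' c in (slow, fast). The two-component model is linear in
#' (si0 * sfSlow, si0 * sfFast) against these two columns, which is what the
#' voxel fit exploits.
#'
#' @param scheme an \code{\link{AcquisitionScheme-class}} object.
#' @param basis a \code{\link{ComponentBasis-class}} object (both ADCs and
#'   both T2s fixed).
#' @return numeric matrix with one row per measurement (canonical (TE, b)
#'   order) and columns \code{slow}, \code{fast}; all entries in (0, 1].
#' @examples
#' attenuationBasis(AcquisitionScheme(), ComponentBasis())
#' @export
attenuationBasis <- function(scheme, basis) {
  stopifnot(is(scheme, "AcquisitionScheme"), is(basis, "ComponentBasis"))
  validObject(basis)
  m <- measurementTable(scheme)
  adc <- adcPair(basis)
  t2 <- t2Pair(basis)
  A <- cbind(
    slow = exp(-m$te / t2[["slow"]] - m$b * adc[["slow"]] * .B_ADC_SCALE),
    fast = exp(-m$te / t2[["fast"]] - m$b * adc[["fast"]] * .B_ADC_SCALE)
  )
  A
}

#' Two-component forward signal
#'
#' The combined T2-diffusion model: each voxel's signal is a mixture of a
#' slow compartment (low ADC, short T2) and a fast compartment (high ADC,
#' long T2),
#' \deqn{SI = SI_0 [SF_{slow} e^{-TE/T2_{slow}} e^{-b\,ADC_{slow}}
#'            + (1 - SF_{slow}) e^{-TE/T2_{fast}} e^{-b\,ADC_{fast}}].}
#' \code{si0} and \code{sfSlow} may be vectors (one voxel per element).
#'
#' @param si0 signal intensity at TE = 0, b = 0 (scanner units, >= 0).
#' @param sfSlow slow-component signal fraction in [0, 1]; the fast fraction
#'   is always 1 - sfSlow.
#' @param scheme an AcquisitionScheme.
#' @param basis a ComponentBasis.
#' @return numeric matrix, one row per measurement, one column per voxel
#'   (dropped to a vector for a single voxel).
#' @examples
#' twoComponentSignal(100, 0.67, AcquisitionScheme(), ComponentBasis())
#' @export
twoComponentSignal <- function(si0, sfSlow, scheme, basis) {
  stopifnot(length(si0) == length(sfSlow),
            all(si0 >= 0), all(sfSlow >= -1e-12 & sfSlow <= 1 + 1e-12))
  A <- attenuationBasis(scheme, basis)
  out <- A %*% rbind(si0 * sfSlow, si0 * (1 - sfSlow))
  if (ncol(out) == 1L) drop(out) else out
}

#' Bi-exponential (ADC-only) forward signal
#'
#' The purely diffusion-weighted two-pool model at a single echo time:
#' \deqn{SI = SI_0 [SF_{slow} e^{-b\,ADC_{slow}}
#'            + (1 - SF_{slow}) e^{-b\,ADC_{fast}}].}
#'
#' @inheritParams twoComponentSignal
#' @param b numeric vector of b-values in s/mm^2.
#' @param basis a ComponentBasis; only its ADC pair is used.
#' @return numeric matrix (b x voxel), dropped to a vector for one voxel.
#' @examples
#' biExponentialSignal(100, 0.42, c(50, 700), ComponentBasis())
#' @export
biExponentialSignal <- function(si0, sfSlow, b, basis) {
  stopifnot(length(si0) == length(sfSlow), all(b >= 0))
  adc <- adcPair(basis)
  A <- cbind(exp(-b * adc[["slow"]] * .B_ADC_SCALE),
             exp(-b * adc[["fast"]] * .B_ADC_SCALE))
  out <- A %*% rbind(si0 * sfSlow, si0 * (1 - sfSlow))
  if (ncol(out) == 1L) drop(out) else out
}

#' Mono-exponential ADC forward signal
#'
#' \deqn{SI = SI_0 e^{-b\,ADC}.}
#'
#' @param si0 signal at b = 0 for the fitted TE.
#' @param adc apparent diffusion coefficient in um^2/ms (may be negative for
#'   out-of-model voxels, upstream of the exclusion rules).
#' @param b numeric vector of b-values in s/mm^2.
#' @return numeric matrix (b x voxel), dropped to a vector for one voxel.
#' @examples
#' monoExponentialSignal(100, 1.0, 700)
#' @export
monoExponentialSignal <- function(si0, adc, b) {
  stopifnot(length(si0) == length(adc), all(b >= 0))
  out <- sweep(exp(outer(-b * .B_ADC_SCALE, adc)), 2, si0, `*`)
  if (ncol(out) == 1L) drop(out) else out
}
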