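# Digital phantom emulating the patient cohort: tissue-class geometry,
# two-component forward signals, Rician magnitude noise with an air region
# for noise-floor estimation, grade labels, train/test splits.

#' Default tissue classes for the phantom
#'
#' Class-level distribution parameters for the slow signal fraction. The
#' means are ordered tumor > bph > normal, consistent with tumors showing
#' focal low ADC and normal peripheral-zone tissue high ADC, and with the
#' classification thresholds sitting between tumor and background means.
#' The spread splits into a patient-level component (between-patient
#' biological variation) and a voxel-level component (within-region
#' heterogeneity).
#'
#' @return data.frame with columns \code{class}, \code{sfMean},
#'   \code{sfPatientSd}, \code{sfVoxelSd}.
#' @examples
#' defaultTissueClasses()
#' @export
defaultTissueClasses <- function() {
  data.frame(
    class = c("tumor", "normal", "bph", "stroma"),
    sfMean = c(0.75, 0.30, 0.65, 0.45),
    sfPatientSd = c(0.06, 0.06, 0.06, 0.03),
    sfVoxelSd = c(0.05, 0.05, 0.07, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Phantom specification
#'
#' Geometry, tissue parameters and noise model for one synthetic patient
#' volume. The grid holds a box-shaped organ region filled with stroma, in
#' which lesion ellipsoids (tumor / normal reference / BPH nodule) are
#' carved depending on the patient type, plus an air slab used as the
#' background region for noise-floor estimation.
#'
#' \code{targetSnr} sets the class-mean signal-to-noise ratio at the
#' least-attenuated measurement (shortest TE, lowest b): the class base
#' si0 is \code{targetSnr * sigma / attenuation(TEmin, bmin)}. On top of the
#' base, each voxel's si0 carries log-normal heterogeneity
#' (\code{si0SdLog}) emulating receive-coil sensitivity profiles and proton
#' density variation; its default is calibrated so that roughly 10\% of
#' tissue-region voxels trip the exclusion rules at the default noise
#' level, the exclusion rate observed in vivo.
#'
#' @param gridDim integer length-3 volume dimensions; default c(24, 24, 6).
#' @param voxelSize mm, default c(2, 2, 3).
#' @param classes data.frame as \code{\link{defaultTissueClasses}}.
#' @param scheme an AcquisitionScheme.
#' @param basis a ComponentBasis: the generating ADC and T2 pairs shared by
#'   all tissue classes (so the pooled T2 calibration target is
#'   well-defined).
#' @param sigma Rician noise sigma in scanner units.
#' @param targetSnr class-mean SNR at (TEmin, bmin).
#' @param si0SdLog sdlog of the per-voxel log-normal si0 heterogeneity.
#' @return a list of class \code{"phantomSpec"}.
#' @examples
#' sp <- phantomSpec()
#' sp$targetSnr
#' @export
phantomSpec <- function(gridDim = c(24, 24, 6), voxelSize = c(2, 2, 3),
                        classes = defaultTissueClasses(),
                        scheme = AcquisitionScheme(),
                        basis = ComponentBasis(),
                        sigma = 1, targetSnr = 40, si0SdLog = 0.8) {
  stopifnot(length(gridDim) == 3, all(gridDim[1:2] >= 12), gridDim[3] >= 4,
            sigma >= 0, targetSnr > 0, si0SdLog >= 0)
  stopifnot(all(c("class", "sfMean", "sfPatientSd", "sfVoxelSd") %in%
                  names(classes)))
  sf <- setNames(classes$sfMean, classes$class)
  if (!(sf[["tumor"]] > sf[["bph"]] && sf[["bph"]] > sf[["normal"]]))
    stop("class means must be ordered sfMean(tumor) > sfMean(bph) > sfMean(normal)")
  if (any(classes$sfMean <= 0 | classes$sfMean >= 1))
    stop("class sfMean values must lie in (0, 1)")
  structure(list(gridDim = as.integer(gridDim), voxelSize = voxelSize,
                 classes = classes, scheme = scheme, basis = basis,
                 sigma = sigma, targetSnr = targetSnr,
                 si0SdLog = si0SdLog),
            class = "phantomSpec")
}

# voxel-center ellipsoid membership on the integer lattice
.ellipsoidMask <- function(gridDim, center, radii) {
  x <- seq_len(gridDim[1]); y <- seq_len(gridDim[2]); z <- seq_len(gridDim[3])
  dx2 <- ((x - center[1]) / radii[1])^2
  dy2 <- ((y - center[2]) / radii[2])^2
  dz2 <- ((z - center[3]) / radii[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# geometry constants (voxel coordinates on the default 24 x 24 x 6 grid,
# scaled proportionally for other grids)
.phantomGeometry <- function(gridDim) {
  sc <- gridDim / c(24, 24, 6)
  list(
    boxLo = pmax(2L, round(c(6, 6, 2) * sc)),
    boxHi = round(c(21, 21, 5) * sc),
    bgHi = pmax(1L, round(c(24, 2, 6) * sc)),   # air slab y <= bgHi[2]
    tumorCenter = c(9, 12, 3.5) * sc,
    normalCenter = c(18, 12, 3.5) * sc,
    bphCenter = c(13.5, 13, 3.5) * sc,
    lesionRadii = c(2.5, 2.5, 1.5) * sc
  )
}

#' Build ground-truth parameter maps and masks for one phantom patient
#'
#' Assigns every voxel exactly one class (air outside the box, stroma
#' inside, lesion ellipsoids carved on top), draws the per-patient class
#' means and per-voxel ground-truth sfSlow and si0, and returns all masks.
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @param type patient type: \code{"cancer_pz"} (tumor + normal reference
#'   region), \code{"cancer_nonpz"} (tumor only) or \code{"bph"} (BPH
#'   nodule only).
#' @param seed integer; fully determines the output.
#' @return list of class \code{"phantomTruth"}: \code{classMap} (integer 3D
#'   array with a \code{levels} attribute), \code{sfSlow} and \code{si0}
#'   ground-truth arrays (NA / 0 in air), \code{masks} (list of logical 3D
#'   arrays: box, background, tumor, normal, bph), \code{patientMeanSf}
#'   (named per-class draws), \code{type}, \code{spec}.
#' @examples
#' ph <- buildPhantom(phantomSpec(), "cancer_pz", seed = 7)
#' sapply(ph$masks, sum)
#' @export
buildPhantom <- function(spec, type = c("cancer_pz", "cancer_nonpz", "bph"),
                         seed = 1) {
  stopifnot(inherits(spec, "phantomSpec"))
  type <- match.arg(type)
  set.seed(seed)
  gd <- spec$gridDim
  geo <- .phantomGeometry(gd)

  idx <- function(lo, hi) {
    a <- array(FALSE, gd)
    a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    a
  }
  box <- idx(geo$boxLo, geo$boxHi)
  background <- idx(c(1, 1, 1), geo$bgHi) & !box

  jitter3 <- function() round(stats::runif(3, -1, 1))
  lesions <- list()
  if (type %in% c("cancer_pz", "cancer_nonpz"))
    lesions$tumor <- .ellipsoidMask(gd, geo$tumorCenter + jitter3(),
                                    geo$lesionRadii) & box
  if (type == "cancer_pz")
    lesions$normal <- .ellipsoidMask(gd, geo$normalCenter + jitter3(),
                                     geo$lesionRadii) & box
  if (type == "bph")
    lesions$bph <- .ellipsoidMask(gd, geo$bphCenter + jitter3(),
                                  geo$lesionRadii) & box

  levels <- c("air", "stroma", "tumor", "normal", "bph")
  classMap <- array(1L, gd)            # air
  classMap[box] <- 2L                  # stroma
  for (nm in names(lesions)) classMap[lesions[[nm]]] <- match(nm, levels)
  attr(classMap, "levels") <- levels

  cls <- spec$classes
  patientMeanSf <- setNames(
    pmin(0.98, pmax(0.02, stats::rnorm(nrow(cls), cls$sfMean,
                                       cls$sfPatientSd))),
    cls$class)

  # class base si0: class-mean SNR = targetSnr at the least-attenuated
  # measurement
  A <- attenuationBasis(spec$scheme, spec$basis)
  m <- measurementTable(spec$scheme)
  ref <- which(m$te == min(m$te) & m$b == min(m$b))
  attRef <- function(sf) sf * A[ref, "slow"] + (1 - sf) * A[ref, "fast"]
  sigmaScale <- if (spec$sigma > 0) spec$sigma else 1
  baseSi0 <- setNames(spec$targetSnr * sigmaScale / attRef(cls$sfMean),
                      cls$class)

  sfSlow <- array(NA_real_, gd)
  si0 <- array(0, gd)
  for (nm in cls$class) {
    vox <- which(classMap == match(nm, levels))
    if (!length(vox)) next
    sfSlow[vox] <- pmin(0.98, pmax(0.02, stats::rnorm(
      length(vox), patientMeanSf[[nm]],
      cls$sfVoxelSd[cls$class == nm])))
    si0[vox] <- baseSi0[[nm]] *
      stats::rlnorm(length(vox), meanlog = 0, sdlog = spec$si0SdLog)
  }

  masks <- list(box = box, background = background,
                tumor = if (!is.null(lesions$tumor)) lesions$tumor else array(FALSE, gd),
                normal = if (!is.null(lesions$normal)) lesions$normal else array(FALSE, gd),
                bph = if (!is.null(lesions$bph)) lesions$bph else array(FALSE, gd))

  structure(list(classMap = classMap, sfSlow = sfSlow, si0 = si0,
                 masks = masks, patientMeanSf = patientMeanSf,
                 type = type, spec = spec),
            class = "phantomTruth")
}

#' Simulate noisy magnitude signals from ground-truth maps
#'
#' Forward-evaluates the two-component model at every voxel (air voxels
#' have si0 = 0, i.e. a clean signal of zero) and applies Rician magnitude
#' noise: \code{sqrt((S + e1)^2 + e2^2)} with e1, e2 independent zero-mean
#' Gaussians of the given sigma. With \code{sigma = 0} the output equals
#' the clean forward signal exactly.
#'
#' @param truth a \code{"phantomTruth"} from \code{\link{buildPhantom}}.
#' @param sigma noise sigma; defaults to the spec's.
#' @param seed integer seed for the noise draw (separate from the geometry
#'   seed, so one geometry can carry independent noise realizations).
#' @return a \code{\link{SignalVolume-class}} object carrying the phantom's
#'   box and background masks.
#' @examples
#' ph <- buildPhantom(phantomSpec(), "bph", seed = 3)
#' vol <- simulateSignals(ph, sigma = 1, seed = 4)
#' @export
simulateSignals <- function(truth, sigma = NULL, seed = 1) {
  stopifnot(inherits(truth, "phantomTruth"))
  spec <- truth$spec
  if (is.null(sigma)) sigma <- spec$sigma
  gd <- spec$gridDim
  nVox <- prod(gd)
  sf <- as.vector(truth$sfSlow)
  si0 <- as.vector(truth$si0)
  sf[is.na(sf)] <- 0                     # air: si0 = 0, fraction irrelevant
  A <- attenuationBasis(spec$scheme, spec$basis)
  clean <- A %*% rbind(si0 * sf, si0 * (1 - sf))   # nMeas x nVox
  if (sigma > 0) {
    set.seed(seed)
    n <- length(clean)
    noisy <- sqrt((clean + stats::rnorm(n, 0, sigma))^2 +
                    stats::rnorm(n, 0, sigma)^2)
  } else {
    noisy <- clean
  }
  dat <- array(t(noisy), dim = c(gd, nrow(A)))
  SignalVolume(dat, spec$scheme, spec$voxelSize,
               boxMask = truth$masks$box,
               backgroundMask = truth$masks$background)
}

#' Cohort specification
#'
#' Cohort structure mirroring the clinical study arms: cancer patients
#' split into training and test sets, plus a benign-hyperplasia arm. Each
#' cancer patient carries one tumor region (plus one normal reference
#' region when the tumor is in the peripheral zone); each BPH patient
#' carries one nodule region. Tumor grade labels (Gleason Grade Group,
#' 1-5) follow a monotone link from the patient's ground-truth tumor mean
#' sfSlow plus label noise.
#'
#' @param nTrain,nTest cancer patients per split (defaults 31/31).
#' @param nBph benign-hyperplasia patients (default 14).
#' @param pzTrain,pzTest how many cancer patients per split have
#'   peripheral-zone tumors (defaults 25/24; the rest are non-PZ).
#' @param phantom a \code{\link{phantomSpec}} shared by all patients.
#' @param gradeNoiseSd sd of the label noise in grade units; 2.0 yields
#'   fair (~0.3-0.5) rank correlations between grade and tumor sfSlow.
#' @param seed master seed; fully determines the cohort.
#' @return a list of class \code{"cohortSpec"}.
#' @export
cohortSpec <- function(nTrain = 31, nTest = 31, nBph = 14,
                       pzTrain = 25, pzTest = 24,
                       phantom = phantomSpec(), gradeNoiseSd = 2.0,
                       seed = 1) {
  stopifnot(nTrain >= 1, nTest >= 1, nBph >= 0,
            pzTrain <= nTrain, pzTest <= nTest,
            seed == as.integer(seed))
  structure(list(nTrain = nTrain, nTest = nTest, nBph = nBph,
                 pzTrain = pzTrain, pzTest = pzTest, phantom = phantom,
                 gradeNoiseSd = gradeNoiseSd, seed = as.integer(seed)),
            class = "cohortSpec")
}

# grade link: affine map of the patient's true tumor mean sfSlow plus
# Gaussian label noise, rounded and clipped to 1..5
.gradeFromSf <- function(sfMean, noiseSd, anchor = 0.75, slopePerSf = 1 / 0.06) {
  raw <- 3 + (sfMean - anchor) * slopePerSf + stats::rnorm(length(sfMean), 0, noiseSd)
  pmin(5L, pmax(1L, as.integer(round(raw))))
}

#' Simulate a full phantom cohort
#'
#' Generates every patient's ground truth and noisy signal volume, the
#' cohort metadata table and the train/test split. Per-patient geometry
#' and noise seeds are derived from the master seed, so the whole cohort is
#' reproducible bit-for-bit and different master seeds give disjoint noise
#' realizations.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return list of class \code{"phantomCohort"}: \code{patients}, a list of
#'   per-patient lists (\code{truth}, \code{volume}, \code{meta} row);
#'   \code{table}, a data.frame with columns patient, arm, split, zone,
#'   ggg, sfTumorTrue; \code{spec}.
#' @examples
#' co <- simulateCohort(cohortSpec(nTrain = 2, nTest = 2, nBph = 1,
#'                                 pzTrain = 1, pzTest = 2))
#' co$table
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  set.seed(spec$seed)
  n <- spec$nTrain + spec$nTest + spec$nBph
  geomSeeds <- sample.int(.Machine$integer.max, n)
  noiseSeeds <- sample.int(.Machine$integer.max, n)

  split <- c(rep("train", spec$nTrain), rep("test", spec$nTest),
             rep("test", spec$nBph))
  arm <- c(rep("cancer", spec$nTrain + spec$nTest), rep("bph", spec$nBph))
  zone <- c(rep(c("PZ", "nonPZ"), c(spec$pzTrain, spec$nTrain - spec$pzTrain)),
            rep(c("PZ", "nonPZ"), c(spec$pzTest, spec$nTest - spec$pzTest)),
            rep("nonPZ", spec$nBph))

  patients <- vector("list", n)
  ggg <- rep(NA_integer_, n)
  sfTumorTrue <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    type <- if (arm[i] == "bph") "bph"
            else if (zone[i] == "PZ") "cancer_pz" else "cancer_nonpz"
    truth <- buildPhantom(spec$phantom, type, seed = geomSeeds[i])
    vol <- simulateSignals(truth, sigma = spec$phantom$sigma,
                           seed = noiseSeeds[i])
    patients[[i]] <- list(truth = truth, volume = vol)
    if (arm[i] == "cancer") sfTumorTrue[i] <- truth$patientMeanSf[["tumor"]]
  }
  cancer <- arm == "cancer"
  ggg[cancer] <- .gradeFromSf(sfTumorTrue[cancer], spec$gradeNoiseSd)

  tab <- data.frame(
    patient = sprintf("P%03d", seq_len(n)),
    arm = arm, split = split, zone = zone, ggg = ggg,
    sfTumorTrue = sfTumorTrue,
    geomSeed = geomSeeds, noiseSeed = noiseSeeds,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) patients[[i]]$meta <- tab[i, ]
  structure(list(patients = patients, table = tab, spec = spec),
            class = "phantomCohort")
}
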