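# Shared fixtures, built in code at test time.

defaultScheme <- function() AcquisitionScheme()
defaultBasis <- function() ComponentBasis()

# a small cohort spec that keeps smoke tests fast; calibration is skipped
# by passing fixedT2 to pipelineConfig where appropriate
tinyCohortSpec <- function(seed = 11) {
  cohortSpec(nTrain = 4, nTest = 4, nBph = 2, pzTrain = 3, pzTest = 3,
             seed = seed)
}

# hand-built 2x2x1-voxel volume: full control over signals and masks.
# signals: list of per-voxel measurement vectors laid out along x
tinyVolume <- function(signals, background = 10, scheme = defaultScheme()) {
  nm <- nMeasurements(scheme)
  nx <- length(signals) + 1          # last x holds the background voxel
  dat <- array(0, c(nx, 1, 1, nm))
  for (i in seq_along(signals)) dat[i, 1, 1, ] <- signals[[i]]
  dat[nx, 1, 1, ] <- background
  box <- array(FALSE, c(nx, 1, 1)); box[seq_along(signals), 1, 1] <- TRUE
  bg <- array(FALSE, c(nx, 1, 1)); bg[nx, 1, 1] <- TRUE
  SignalVolume(dat, scheme, boxMask = box, backgroundMask = bg)
}
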