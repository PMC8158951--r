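sch <- defaultScheme()
bas <- defaultBasis()

test_that("exclusion boundary: equal to three times the noise floor excludes, strictly above keeps", {
  atBoundary <- c(100, 80, 60, 30)      # one measurement exactly 3 x 10
  justAbove <- c(100, 80, 60, 30.1)
  vol <- tinyVolume(list(atBoundary, justAbove), background = 10)
  ex <- buildExclusionMask(vol)
  expect_equal(ex$qc$noiseFloor, 10)
  expect_false(ex$keep[1, 1, 1])
  expect_true(ex$keep[2, 1, 1])
  expect_equal(ex$qc$nBelowNoiseFloor, 1)
})

test_that("negative apparent decays are excluded by sign, equality is kept", {
  risingB <- c(100, 80, 70, 75)        # S(73, b700) > S(73, b50)
  risingTe <- c(100, 80, 101, 60)      # S(te73, b50) > S(te55, b50)
  flatB <- c(100, 80, 90, 80)          # zero apparent ADC at TE 73: kept
  vol <- tinyVolume(list(risingB, risingTe, flatB), background = 1)
  ex <- buildExclusionMask(vol)
  expect_false(ex$keep[1, 1, 1])
  expect_false(ex$keep[2, 1, 1])
  expect_true(ex$keep[3, 1, 1])
  expect_equal(ex$qc$nNegativeAdc, 1)
  expect_equal(ex$qc$nNegativeT2, 1)
})

test_that("an empty background region is rejected by name", {
  vol <- tinyVolume(list(c(100, 80, 60, 40)))
  vol@backgroundMask[] <- FALSE
  expect_error(buildExclusionMask(vol), "background")
})

test_that("two-component voxel fit recovers noise-free parameters", {
  # pure slow voxel
  f <- fitTwoComponentVoxel(twoComponentSignal(100, 1, sch, bas), sch, bas)
  expect_equal(f$si0, 100, tolerance = 1e-9)
  expect_equal(f$sfSlow, 1, tolerance = 1e-12)
  expect_equal(f$rmse, 0, tolerance = 1e-6)

  f <- fitTwoComponentVoxel(twoComponentSignal(100, 0.67, sch, bas), sch, bas)
  expect_equal(f$si0, 100, tolerance = 1e-6)
  expect_equal(f$sfSlow, 0.67, tolerance = 1e-6)

  # degenerate inputs
  expect_false(fitTwoComponentVoxel(rep(0, 4), sch, bas)$valid)
  expect_false(fitTwoComponentVoxel(c(1, NA, 1, 1), sch, bas)$valid)
})

test_that("non-negativity clamps the fraction into [0, 1] for out-of-model signals", {
  s <- twoComponentSignal(100, 0, sch, bas)
  s[1] <- s[1] + 300                   # large positive spike on one measurement
  f <- fitTwoComponentVoxel(s, sch, bas)
  expect_gte(f$sfSlow, 0)
  expect_lte(f$sfSlow, 1)
})

test_that("constrained linear solve agrees with the exhaustive fraction scan", {
  set.seed(71)
  for (i in 1:100) {
    s <- twoComponentSignal(runif(1, 40, 160), runif(1), sch, bas) +
      rnorm(4, 0, 2)
    s <- pmax(s, 0.1)
    f <- fitTwoComponentVoxel(s, sch, bas)
    o <- oracleScanTwoComponent(s, sch, bas, step = 1e-4)
    expect_lt(abs(f$sfSlow - o$sfSlow), 1e-4)
  }
})

test_that("bi-exponential two-point fit matches the bisection oracle and clips rising signals", {
  s <- biExponentialSignal(1, 0.42, c(50, 700), bas)
  f <- fitBiExponentialVoxel(s[1], s[2], 50, 700, bas)
  expect_equal(f$sfSlow, 0.42, tolerance = 1e-9)
  expect_equal(f$si0, 1, tolerance = 1e-9)
  o <- oracleBisectBiExp(s[1], s[2], 50, 700, 0.3, 2.6)
  expect_equal(f$sfSlow, o, tolerance = 1e-8)

  f1 <- fitBiExponentialVoxel(biExponentialSignal(50, 1, 50, bas),
                              biExponentialSignal(50, 1, 700, bas),
                              50, 700, bas)
  expect_equal(f1$sfSlow, 1, tolerance = 1e-12)

  # a rising b-decay lies beyond even the pure-slow attenuation, so the
  # solution clips to the slow boundary and the voxel is flagged
  rising <- fitBiExponentialVoxel(80, 90, 50, 700, bas)
  expect_equal(rising$sfSlow, 1)
  expect_false(rising$valid)
  expect_false(fitBiExponentialVoxel(0, 10, 50, 700, bas)$valid)
})

test_that("mono-exponential closed form is exact and passes the sign through", {
  expect_equal(fitMonoAdcVoxel(77, 77, 50, 700)$adc, 0, tolerance = 1e-12)
  f <- fitMonoAdcVoxel(100, 52.205, 50, 700)
  expect_equal(f$adc, 1.000, tolerance = 1e-4)
  neg <- fitMonoAdcVoxel(50, 70, 50, 700)
  expect_lt(neg$adc, 0)
  expect_false(neg$valid)
  expect_false(fitMonoAdcVoxel(-1, 10, 50, 700)$valid)
})

test_that("volume fit equals the ground truth on a noiseless phantom and is voxel-order independent", {
  ph <- buildPhantom(phantomSpec(si0SdLog = 0), "cancer_pz", seed = 5)
  vol <- simulateSignals(ph, sigma = 0)
  fm <- fitVolume(vol, "twoComponent", bas)
  ok <- validMask(fm)
  expect_true(any(ok))
  expect_equal(fitMap(fm, "sfSlow")[ok], ph$sfSlow[ok], tolerance = 1e-6)
  expect_equal(fitMap(fm, "si0")[ok], ph$si0[ok], tolerance = 1e-6)

  # invalid voxels are NA, never zero
  expect_true(all(is.na(fitMap(fm, "sfSlow")[!ok])))

  # per-voxel independence: results match the scalar fit at scattered voxels
  set.seed(8)
  for (v in sample(which(ok), 5)) {
    ijk <- arrayInd(v, dim(ok))
    s <- volumeData(vol)[ijk[1], ijk[2], ijk[3], ]
    expect_equal(fitMap(fm, "sfSlow")[v],
                 fitTwoComponentVoxel(s, sch, bas)$sfSlow, tolerance = 1e-9)
  }
})

test_that("QC excluded counts match a brute-force recount of the rules", {
  ph <- buildPhantom(phantomSpec(), "bph", seed = 9)
  vol <- simulateSignals(ph, sigma = 1, seed = 10)
  ex <- buildExclusionMask(vol)
  expect_equal(ex$qc$nExcluded, bruteExclusionCount(vol))
  expect_equal(ex$qc$nExcluded + sum(ex$keep), ex$qc$nBox)
})

test_that("fraction recovery improves monotonically as SNR doubles", {
  set.seed(12)
  n <- 1000
  sfTrue <- runif(n, 0.1, 0.9)
  A <- attenuationBasis(sch, bas)
  medErr <- sapply(c(10, 20, 40, 80), function(snr) {
    si0 <- snr / (sfTrue * A[1, "slow"] + (1 - sfTrue) * A[1, "fast"])
    clean <- A %*% rbind(si0 * sfTrue, si0 * (1 - sfTrue))
    noisy <- sqrt((clean + rnorm(length(clean)))^2 + rnorm(length(clean))^2)
    f <- t2dwi:::.fitTwoComponentMatrix(noisy, A)
    median(abs(f$sfSlow - sfTrue), na.rm = TRUE)
  })
  expect_true(all(diff(medErr) < 0))
})
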