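test_that("phantom geometry is consistent: lesions inside the box, background outside", {
  for (type in c("cancer_pz", "cancer_nonpz", "bph")) {
    ph <- buildPhantom(phantomSpec(), type, seed = 3)
    m <- ph$masks
    expect_true(all(m$tumor[m$tumor] & m$box[m$tumor]))
    expect_false(any(m$background & m$box))
    lesions <- m$tumor | m$normal | m$bph
    expect_true(all(m$box[lesions]))
    expect_false(any(m$background & lesions))
    # roi multiplicity per patient type
    expect_equal(any(m$tumor), type != "bph")
    expect_equal(any(m$normal), type == "cancer_pz")
    expect_equal(any(m$bph), type == "bph")
    # tumor and normal reference regions never overlap
    expect_false(any(m$tumor & m$normal))
    # every voxel has exactly one class
    expect_true(all(ph$classMap %in% 1:5))
  }
})

test_that("zero spread collapses the truth to piecewise-constant class means", {
  cls <- defaultTissueClasses()
  cls$sfPatientSd <- 0; cls$sfVoxelSd <- 0
  ph <- buildPhantom(phantomSpec(classes = cls, si0SdLog = 0),
                     "cancer_pz", seed = 4)
  lv <- attr(ph$classMap, "levels")
  for (nm in c("tumor", "normal", "stroma")) {
    vox <- ph$classMap == match(nm, lv)
    expect_equal(unique(ph$sfSlow[vox]), cls$sfMean[cls$class == nm],
                 tolerance = 1e-12)
  }
  expect_true(all(ph$si0[ph$classMap == 1] == 0))   # air carries no signal
})

test_that("lesion voxel counts match the analytic ellipsoid volume up to discretization", {
  counts <- sapply(1:10, function(s)
    sum(buildPhantom(phantomSpec(), "cancer_pz", seed = s)$masks$tumor))
  analytic <- 4 / 3 * pi * 2.5 * 2.5 * 1.5
  expect_lt(abs(mean(counts) - analytic) / analytic, 0.35)
})

test_that("simulated signals are exact at sigma zero and reproducible under the seed", {
  ph <- buildPhantom(phantomSpec(), "cancer_pz", seed = 5)
  volClean <- simulateSignals(ph, sigma = 0)
  # clean forward signal equals the model evaluated at the truth maps
  sch <- ph$spec$scheme; bas <- ph$spec$basis
  v <- which(ph$masks$tumor)[1]
  ijk <- arrayInd(v, dim(ph$sfSlow))
  expect_equal(volumeData(volClean)[ijk[1], ijk[2], ijk[3], ],
               twoComponentSignal(ph$si0[v], ph$sfSlow[v], sch, bas),
               tolerance = 1e-12)
  expect_true(all(volumeData(volClean)[, , , 1][ph$classMap == 1] == 0))

  vol1 <- simulateSignals(ph, sigma = 1, seed = 6)
  vol2 <- simulateSignals(ph, sigma = 1, seed = 6)
  expect_identical(volumeData(vol1), volumeData(vol2))
  vol3 <- simulateSignals(ph, sigma = 1, seed = 7)
  expect_false(identical(volumeData(vol1), volumeData(vol3)))
})

test_that("Rician magnitude noise is unbiased for bright voxels within Monte-Carlo error", {
  # magnitude mean for S >> sigma: approx S + sigma^2/(2 S); at S = 100 and
  # sigma = 1 the bias (0.005) is far below the Monte-Carlo standard error
  set.seed(8)
  n <- 1e4
  S <- 100
  noisy <- sqrt((S + rnorm(n))^2 + rnorm(n)^2)
  se <- sd(noisy) / sqrt(n)
  expect_lt(abs(mean(noisy) - S), 3 * se + S * 1e-4)
})

test_that("cohort structure mirrors the configured arms, splits and ROI multiplicities", {
  spec <- cohortSpec(nTrain = 5, nTest = 4, nBph = 3, pzTrain = 3,
                     pzTest = 2, seed = 30)
  co <- simulateCohort(spec)
  tab <- co$table
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$arm == "cancer" & tab$split == "train"), 5)
  expect_equal(sum(tab$arm == "cancer" & tab$split == "test"), 4)
  expect_equal(sum(tab$arm == "bph"), 3)
  expect_equal(sum(tab$zone == "PZ" & tab$split == "train"), 3)
  expect_equal(sum(tab$zone == "PZ" & tab$split == "test"), 2)
  for (i in seq_len(nrow(tab))) {
    m <- co$patients[[i]]$truth$masks
    expect_equal(any(m$tumor), tab$arm[i] == "cancer")
    expect_equal(any(m$normal), tab$arm[i] == "cancer" & tab$zone[i] == "PZ")
    expect_equal(any(m$bph), tab$arm[i] == "bph")
  }
  expect_true(all(tab$ggg[tab$arm == "cancer"] %in% 1:5))
  expect_true(all(is.na(tab$ggg[tab$arm == "bph"])))

  # same master seed reproduces the cohort bit-for-bit
  co2 <- simulateCohort(spec)
  expect_identical(volumeData(co2$patients[[1]]$volume),
                   volumeData(co$patients[[1]]$volume))
  expect_identical(co2$table, co$table)
})

test_that("grade labels correlate positively with the true tumor fraction across seeds", {
  rhos <- sapply(1:20, function(s) {
    tab <- simulateCohort(cohortSpec(nTrain = 31, nTest = 31, nBph = 0,
                                     phantom = phantomSpec(gridDim = c(12, 12, 4)),
                                     seed = s))$table
    cancer <- tab$arm == "cancer"
    suppressWarnings(cor(tab$sfTumorTrue[cancer], tab$ggg[cancer],
                         method = "spearman"))
  })
  expect_true(all(rhos > 0))
  expect_gt(mean(rhos), 0.25)
})

test_that("the noiseless pipeline recovers the class means end to end", {
  cls <- defaultTissueClasses()
  cls$sfPatientSd <- 0; cls$sfVoxelSd <- 0
  ph <- phantomSpec(classes = cls, sigma = 0, si0SdLog = 0)
  truth <- buildPhantom(ph, "cancer_pz", seed = 40)
  vol <- simulateSignals(truth, sigma = 0)
  fits <- list(twoComponent = fitVolume(vol, "twoComponent",
                                        ComponentBasis()))
  for (roi in c("tumor", "normal")) {
    row <- roiSummary(fits, truth$masks[[roi]], roi)
    expect_equal(row$sfTwoComponent, cls$sfMean[cls$class == roi],
                 tolerance = 1e-3)
  }
})
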