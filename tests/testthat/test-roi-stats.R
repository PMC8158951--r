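test_that("ROI summary means match brute-force recomputation and degenerate ROIs error by name", {
  ph <- buildPhantom(phantomSpec(), "cancer_pz", seed = 14)
  vol <- simulateSignals(ph, sigma = 1, seed = 15)
  fm <- fitVolume(vol, "twoComponent")
  row <- roiSummary(list(twoComponent = fm), ph$masks$tumor, "tumor")
  ok <- validMask(fm) & ph$masks$tumor
  vals <- fitMap(fm, "sfSlow")
  expect_equal(row$sfTwoComponent, sum(vals[ok]) / sum(ok), tolerance = 1e-12)
  expect_equal(row$nValid, sum(ok))

  # single-voxel mask
  one <- array(FALSE, dim(ok)); one[which(ok)[1]] <- TRUE
  expect_equal(roiSummary(list(twoComponent = fm), one, "x")$sfTwoComponent,
               vals[which(ok)[1]])

  # an all-excluded ROI is reported by name
  dead <- array(FALSE, dim(ok)); dead[which(!validMask(fm))[1]] <- TRUE
  expect_error(roiSummary(list(twoComponent = fm), dead, "necrotic"),
               "necrotic")
})

test_that("signed-rank p-values agree with enumeration over all sign assignments", {
  # all-positive (untied) differences, n = 10: p = 2/2^10
  x <- 1:10 + (1:10) / 10; y <- 1:10
  expect_equal(pairedTest(x, y), 2 / 2^10, tolerance = 1e-12)

  set.seed(41)
  for (n in c(5, 7, 9, 10)) {
    for (rep in 1:5) {
      d <- round(rnorm(n, 0.3, 1), 3)
      d <- d[d != 0]; d <- d[!duplicated(abs(d))]
      if (length(d) < 3) next
      y0 <- seq_along(d)
      expect_equal(pairedTest(y0 + d, y0), enumSignedRankP(d),
                   tolerance = 1e-12)
    }
  }
  expect_warning(p <- pairedTest(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(p, 1)
})

test_that("rank-sum p-values agree with enumeration over all group assignments", {
  # complete separation 3 vs 3: 2/choose(6,3)
  expect_equal(unpairedTest(c(4, 5, 6), c(1, 2, 3)), 0.1, tolerance = 1e-12)
  expect_equal(unpairedTest(c(2, 4), c(2, 4)), 1)

  set.seed(42)
  for (sizes in list(c(4, 4), c(5, 3), c(6, 4), c(5, 5))) {
    for (rep in 1:5) {
      x <- round(rnorm(sizes[1], 0.5), 3)
      y <- round(rnorm(sizes[2]), 3)
      if (anyDuplicated(c(x, y))) next
      expect_equal(unpairedTest(x, y), enumMannWhitneyP(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("Bonferroni adjustment reproduces the working significance levels", {
  a9 <- adjustedAlpha(0.05, 9)
  expect_equal(a9$alpha, 0.05 / 9, tolerance = 1e-12)
  expect_equal(a9$displayed, 0.006)
  expect_equal(adjustedAlpha(0.05, 1)$alpha, 0.05)
  expect_equal(adjustedAlpha(0.05, 26, digits = 4)$displayed, 0.0019)
})

test_that("rank AUC equals brute-force pairwise comparison, including ties and polarity", {
  expect_equal(rocAnalysis(c(3, 2), c(1, 2))$auc, 0.875, tolerance = 1e-12)
  expect_equal(rocAnalysis(c(10, 20), c(1, 2))$auc, 1.0)

  set.seed(43)
  for (i in 1:100) {
    pos <- round(rnorm(sample(3:30, 1), 0.8), 1)   # rounding induces ties
    neg <- round(rnorm(sample(3:30, 1)), 1)
    a <- rocAnalysis(pos, neg)$auc
    expect_equal(a, bruteAuc(pos, neg), tolerance = 1e-12)
    expect_equal(rocAnalysis(pos, neg, "lower")$auc, 1 - a,
                 tolerance = 1e-12)
  }
})

test_that("rank AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  pos <- rnorm(50, 1); neg <- rnorm(80)
  a <- rocAnalysis(pos, neg)$auc
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 50), rep(0, 80)), predictor = c(pos, neg),
    direction = "<", quiet = TRUE))
  expect_equal(a, as.numeric(ref), tolerance = 1e-12)
})

test_that("AUC equals the scaled rank-sum statistic", {
  set.seed(45)
  x <- rnorm(12, 1); y <- rnorm(15)
  U <- suppressWarnings(stats::wilcox.test(x, y)$statistic)
  expect_equal(rocAnalysis(x, y)$auc, unname(U) / (12 * 15),
               tolerance = 1e-12)
})

test_that("the training threshold maximizes Youden's J and transfers without touching test labels", {
  # small example checked against an exhaustive threshold scan
  trainPos <- c(0.9, 0.8, 0.7); trainNeg <- c(0.6, 0.5, 0.4)
  dg <- thresholdTransfer(trainPos, trainNeg, c(0.75, 0.85), c(0.3, 0.72))
  expect_equal(dg$threshold, 0.7)
  expect_equal(dg$sensitivity, 100)
  expect_equal(dg$specificity, 50)

  set.seed(46)
  pos <- rnorm(40, 1); neg <- rnorm(60)
  dg <- thresholdTransfer(pos, neg, rnorm(30, 1), rnorm(50))
  cand <- sort(unique(c(pos, neg)))
  J <- vapply(cand, function(t) mean(pos >= t) - mean(neg >= t), numeric(1))
  expect_equal(mean(pos >= dg$threshold) - mean(neg >= dg$threshold),
               max(J), tolerance = 1e-12)

  # J-ties break toward calling fewer voxels tumor (the larger cut for
  # higher-is-tumor polarity)
  tie <- thresholdTransfer(c(2, 3), c(0, 1), c(2, 3), c(0, 1))
  expect_equal(tie$threshold, 2)

  # permuting test labels changes test performance, never the threshold
  dg2 <- thresholdTransfer(pos, neg, rnorm(50), rnorm(30, 1))
  expect_equal(dg2$threshold, dg$threshold)

  # perfectly separated train = test
  sep <- thresholdTransfer(c(5, 6), c(1, 2), c(5, 6), c(1, 2))
  expect_equal(sep$sensitivity, 100)
  expect_equal(sep$specificity, 100)

  # lower-is-tumor polarity mirrors the rule
  lo <- thresholdTransfer(c(1, 2), c(5, 6), c(1, 2), c(5, 6), "lower")
  expect_equal(lo$sensitivity, 100)
  expect_equal(lo$specificity, 100)
})

test_that("Spearman correlation handles ties by mid-rank and negates under reversal", {
  expect_equal(spearmanGradeCorrelation(1:6, c(2, 3, 5, 7, 11, 13))$rho, 1)
  v <- c(0.1, 0.4, 0.4, 0.7, 0.9)
  g <- c(1, 2, 3, 3, 5)
  # hand-ranked: mid-ranks for the tied values
  rv <- c(1, 2.5, 2.5, 4, 5); rg <- c(1, 2, 3.5, 3.5, 5)
  expect_equal(spearmanGradeCorrelation(v, g)$rho, cor(rv, rg),
               tolerance = 1e-12)
  expect_equal(spearmanGradeCorrelation(-v, g)$rho,
               -spearmanGradeCorrelation(v, g)$rho, tolerance = 1e-12)
})
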