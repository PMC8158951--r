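sch <- defaultScheme()

test_that("pooled cost is zero at the generating pair, additive, and identifiable", {
  bas <- ComponentBasis(0.3, 2.6, 45, 180)
  set.seed(21)
  S <- twoComponentSignal(runif(100, 40, 160), runif(100), sch, bas)
  expect_lt(gridCost(S, sch, bas), 1e-6)

  # additivity over voxels
  S1 <- S[, 1:40]; S2 <- S[, 41:100]
  noisy <- pmax(S + rnorm(length(S), 0, 3), 0.1)
  expect_equal(gridCost(noisy, sch, bas),
               gridCost(noisy[, 1:40], sch, bas) +
                 gridCost(noisy[, 41:100], sch, bas), tolerance = 1e-9)

  # any wrong T2 pair costs more on noise-free data
  for (t2 in list(c(30, 180), c(45, 250), c(60, 120))) {
    wrong <- ComponentBasis(0.3, 2.6, t2[1], t2[2])
    expect_gt(gridCost(S, sch, wrong), gridCost(S, sch, bas))
  }
  expect_error(gridCost(S[, 0], sch, bas), "empty")
})

test_that("grid search recovers an in-grid generating pair exactly on noise-free voxels", {
  bas <- ComponentBasis(0.3, 2.6, 45, 180)
  set.seed(22)
  S <- twoComponentSignal(runif(500, 40, 160), runif(500), sch, bas)
  surf <- calibrateT2(S, sch)
  expect_equal(unname(optimalT2(surf)), c(45, 180))
  expect_lt(minimumCost(surf), 1e-6)
  expect_equal(nVoxels(surf), 500L)

  # one-cell grid returns that cell
  one <- calibrateT2(S, sch, t2SlowGrid = 40, t2FastGrid = 200)
  expect_equal(unname(optimalT2(one)), c(40, 200))
})

test_that("cost scales linearly with the signals and the optimum location is scale invariant", {
  bas <- ComponentBasis(0.3, 2.6, 45, 180)
  set.seed(23)
  S <- twoComponentSignal(runif(80, 40, 160), runif(80), sch, bas)
  S <- pmax(S + rnorm(length(S), 0, 2), 0.1)
  surf1 <- calibrateT2(S, sch, t2SlowGrid = seq(30, 60, 15),
                       t2FastGrid = seq(140, 220, 40))
  surf7 <- calibrateT2(7 * S, sch, t2SlowGrid = seq(30, 60, 15),
                       t2FastGrid = seq(140, 220, 40))
  expect_equal(costMatrix(surf7), 7 * costMatrix(surf1), tolerance = 1e-9)
  expect_equal(optimalT2(surf7), optimalT2(surf1))
})

test_that("surface normalization scales the maximum to one, idempotently, argmin unchanged", {
  bas <- ComponentBasis(0.3, 2.6, 45, 180)
  set.seed(24)
  S <- twoComponentSignal(runif(60, 40, 160), runif(60), sch, bas)
  S <- pmax(S + rnorm(length(S), 0, 2), 0.1)
  surf <- calibrateT2(S, sch)
  norm1 <- normalizeCostSurface(surf)
  expect_equal(max(costMatrix(norm1), na.rm = TRUE), 1.0, tolerance = 1e-12)
  expect_equal(optimalT2(norm1), optimalT2(surf))
  norm2 <- normalizeCostSurface(norm1)
  expect_equal(costMatrix(norm2), costMatrix(norm1), tolerance = 1e-12)
})

test_that("infeasible cells (t2Slow >= t2Fast) stay unpopulated and ties break deterministically", {
  bas <- ComponentBasis(0.3, 2.6, 45, 180)
  set.seed(25)
  S <- twoComponentSignal(runif(30, 40, 160), runif(30), sch, bas)
  surf <- calibrateT2(S, sch, t2SlowGrid = c(80, 100, 120),
                      t2FastGrid = c(100, 120, 300))
  cm <- costMatrix(surf)
  expect_true(all(is.na(cm[cbind(c(2, 3, 3), c(1, 1, 2))])))
  expect_true(all(!is.na(cm[cbind(c(1, 1, 1, 2, 2, 3), c(1, 2, 3, 2, 3, 3))])))

  # exact tie: a flat surface returns the smallest t2Slow then t2Fast
  flat <- t2dwi:::.costSurface(c(30, 40), c(100, 200),
                               matrix(c(5, 5, 5, 5), 2, 2), 10L)
  expect_equal(unname(optimalT2(flat)), c(30, 100))
})

test_that("noisy calibration at moderate SNR lands within one grid step of the truth", {
  # 500 voxels, SNR 40 at the least-attenuated measurement, 6 seeded repeats
  # (the full 20-repeat Monte-Carlo lives in the acceptance suite)
  bas <- ComponentBasis(0.3, 2.6, 45, 180)
  A <- attenuationBasis(sch, bas)
  hits <- 0
  for (seed in 1:6) {
    set.seed(seed)
    sf <- runif(500, 0.1, 0.9)
    si0 <- 40 / (sf * A[1, "slow"] + (1 - sf) * A[1, "fast"])
    clean <- A %*% rbind(si0 * sf, si0 * (1 - sf))
    noisy <- sqrt((clean + rnorm(length(clean)))^2 + rnorm(length(clean))^2)
    opt <- optimalT2(calibrateT2(noisy, sch))
    if (abs(opt[["t2Slow"]] - 45) <= 5 && abs(opt[["t2Fast"]] - 180) <= 10)
      hits <- hits + 1
  }
  expect_gte(hits, 5)
})
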