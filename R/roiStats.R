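# Region summaries and the cohort-level statistical evaluation: paired and
# unpaired rank tests with Bonferroni adjustment, voxel-wise ROC with a
# training-derived threshold transferred to the test set, and Spearman
# correlation of tumor region means with grade.

#' Summarize fitted maps over one region of interest
#'
#' Means are computed over valid (fitted) voxels only; excluded voxels are
#' never silently treated as zero.
#'
#' @param fits named list of \code{\link{FitMaps-class}} objects, e.g.
#'   \code{list(twoComponent = ..., biExponential = ..., mono = ...)}.
#' @param mask logical 3D array delineating the region.
#' @param roiName label used in the output and in error messages.
#' @return one-row data.frame with \code{roi}, \code{nValid}, and one mean
#'   column per model: \code{sfTwoComponent}, \code{sfBiExponential},
#'   \code{adcMono} (whichever models are present).
#' @examples
#' ph <- buildPhantom(phantomSpec(), "cancer_pz", seed = 1)
#' vol <- simulateSignals(ph, sigma = 0)
#' fm <- fitVolume(vol, "twoComponent")
#' roiSummary(list(twoComponent = fm), ph$masks$tumor, "tumor")
#' @export
roiSummary <- function(fits, mask, roiName = "roi") {
  stopifnot(is.list(fits), length(fits) >= 1)
  out <- data.frame(roi = roiName, stringsAsFactors = FALSE)
  nValid <- NA_integer_
  for (nm in names(fits)) {
    fm <- fits[[nm]]
    stopifnot(is(fm, "FitMaps"))
    ok <- validMask(fm) & mask
    if (!any(ok))
      stop("ROI '", roiName, "' has no valid voxels after exclusion")
    nValid <- sum(ok)
    col <- switch(modelName(fm),
                  twoComponent = "sfTwoComponent",
                  biExponential = "sfBiExponential",
                  mono = "adcMono")
    metric <- switch(modelName(fm),
                     twoComponent = "sfSlow",
                     biExponential = "sfSlow",
                     mono = "adc")
    out[[col]] <- mean(fitMap(fm, metric)[ok])
  }
  out$nValid <- nValid
  out
}

#' Paired two-sided rank test (Wilcoxon signed-rank)
#'
#' Wraps \code{stats::wilcox.test(paired = TRUE)}: zero differences are
#' dropped (Wilcoxon's original rule), the exact distribution is used for
#' n <= 25 non-zero pairs (falling back to the normal approximation in the
#' presence of ties), and the normal approximation above. Identical lists
#' leave the statistic undefined; p = 1 is reported with a warning.
#'
#' @param x,y equal-length paired measurements (same patients, same order).
#' @return two-sided p-value.
#' @examples
#' pairedTest(1:10 + 0.5, 1:10)   # all differences positive: p = 2/2^10
#' @export
pairedTest <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  d <- x - y
  nNonZero <- sum(d != 0)
  if (nNonZero == 0) {
    warning("all paired differences are zero; test undefined, reporting p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = nNonZero <= 25,
                       correct = TRUE)$p.value
  )
}

#' Unpaired two-sided rank test (Mann-Whitney U)
#'
#' Exact for small samples, normal approximation (with continuity
#' correction) for larger ones or in the presence of ties.
#'
#' @param x,y independent samples.
#' @return two-sided p-value.
#' @examples
#' unpairedTest(c(4, 5, 6), c(1, 2, 3))   # complete separation: p = 0.1
#' @export
unpairedTest <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(x) == length(y) && all(sort(x) == sort(y))) return(1)
  suppressWarnings(
    stats::wilcox.test(x, y, exact = length(x) <= 25 && length(y) <= 25,
                       correct = TRUE)$p.value
  )
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons.
#' @param digits decimals used for the displayed (rounded) level.
#' @return list with \code{alpha} (exact, alpha/m) and \code{displayed}
#'   (rounded to \code{digits}).
#' @examples
#' adjustedAlpha(0.05, 9)   # 0.00556, displayed 0.006
#' @export
adjustedAlpha <- function(alpha = 0.05, m = 1, digits = 3) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  a <- alpha / m
  list(alpha = a, displayed = round(a, digits))
}

# orient values so that larger always means "more tumor-like"
.orient <- function(v, polarity) {
  if (polarity == "lower") -v else v
}

#' Voxel-wise ROC analysis
#'
#' AUC via the rank (Mann-Whitney) formulation with tie correction
#' (mid-ranks; a tied pair counts 1/2), plus the full ROC curve with one
#' point per distinct threshold. \code{polarity} states which direction is
#' tumor-like: \code{"higher"} for signal fractions, \code{"lower"} for
#' ADC (a voxel must fall below the threshold to be called tumor).
#'
#' @param tumorValues,nonTumorValues numeric vectors of per-voxel metric
#'   values; both non-empty.
#' @param polarity \code{"higher"} or \code{"lower"} (is tumor).
#' @return list with \code{auc}, \code{polarity} and \code{curve}, a
#'   data.frame (threshold, tpr, fpr) on the original metric scale; the
#'   classification rule is value >= threshold (polarity "higher") or
#'   value <= threshold (polarity "lower").
#' @examples
#' rocAnalysis(c(3, 2), c(1, 2))$auc   # ties count 1/2: 0.875
#' @export
rocAnalysis <- function(tumorValues, nonTumorValues,
                        polarity = c("higher", "lower")) {
  polarity <- match.arg(polarity)
  stopifnot(length(tumorValues) >= 1, length(nonTumorValues) >= 1,
            all(is.finite(tumorValues)), all(is.finite(nonTumorValues)))
  wPos <- .orient(tumorValues, polarity)
  wNeg <- .orient(nonTumorValues, polarity)
  n1 <- length(wPos); n2 <- length(wNeg)
  r <- rank(c(wPos, wNeg))               # mid-ranks handle ties
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)

  cuts <- sort(unique(c(wPos, wNeg)), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) mean(wPos >= c), numeric(1))
  fpr <- vapply(cuts, function(c) mean(wNeg >= c), numeric(1))
  thr <- if (polarity == "lower") -cuts else cuts
  list(auc = auc, polarity = polarity,
       curve = data.frame(threshold = thr, tpr = tpr, fpr = fpr))
}

#' Train an optimal threshold and transfer it to a test set
#'
#' The optimal threshold maximizes Youden's J (sensitivity + specificity
#' - 1) over the training voxels; ties in J are broken toward the threshold
#' classifying fewer voxels as tumor (the more conservative cut). Test-set
#' sensitivity and specificity are computed at that fixed threshold; the
#' reported AUC is the test-set ROC area. Test labels never inform the
#' threshold.
#'
#' @param trainTumor,trainNonTumor training-set voxel values.
#' @param testTumor,testNonTumor test-set voxel values.
#' @inheritParams rocAnalysis
#' @return list: \code{auc} (test set), \code{threshold} (training-derived,
#'   original scale), \code{sensitivity}, \code{specificity} (test set, %),
#'   \code{polarity}, \code{trainAuc}.
#' @examples
#' thresholdTransfer(c(3, 4), c(1, 2), c(3.5, 5), c(0.5, 2.5))
#' @export
thresholdTransfer <- function(trainTumor, trainNonTumor,
                              testTumor, testNonTumor,
                              polarity = c("higher", "lower")) {
  polarity <- match.arg(polarity)
  trainRoc <- rocAnalysis(trainTumor, trainNonTumor, polarity)
  wCut <- .orient(trainRoc$curve$threshold, polarity)
  J <- trainRoc$curve$tpr - trainRoc$curve$fpr
  best <- which(J >= max(J) - 1e-12)
  cut <- max(wCut[best])                 # fewest voxels called tumor
  wPos <- .orient(testTumor, polarity)
  wNeg <- .orient(testNonTumor, polarity)
  testRoc <- rocAnalysis(testTumor, testNonTumor, polarity)
  list(auc = testRoc$auc,
       threshold = if (polarity == "lower") -cut else cut,
       sensitivity = 100 * mean(wPos >= cut),
       specificity = 100 * mean(wNeg < cut),
       polarity = polarity,
       trainAuc = trainRoc$auc)
}

#' Spearman correlation of tumor region means with grade
#'
#' Average ranks for ties; two-sided p-value via the t approximation.
#'
#' @param values per-patient tumor region means.
#' @param ggg Gleason Grade Group labels (1-5), same patients.
#' @return list with \code{rho} and \code{p}.
#' @examples
#' spearmanGradeCorrelation(c(0.6, 0.7, 0.8, 0.9), c(1, 2, 3, 5))
#' @export
spearmanGradeCorrelation <- function(values, ggg) {
  stopifnot(length(values) == length(ggg), length(values) >= 3)
  ct <- suppressWarnings(
    stats::cor.test(values, ggg, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}
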