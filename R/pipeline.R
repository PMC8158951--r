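# End-to-end orchestration on a phantom cohort: exclusion -> pooled T2
# calibration on the training split -> all three model fits -> ROI
# summaries -> statistics, with every table persisted when an output
# directory is configured.

#' Pipeline configuration
#'
#' Either a calibration grid (the default) or a fixed T2 pair must be
#' present; supplying \code{fixedT2} skips the grid search. The
#' configuration round-trips through JSON unchanged (see
#' \code{\link{writePipelineConfig}}).
#'
#' @param cohort a \code{\link{cohortSpec}} describing the phantom cohort.
#' @param adcPair fixed (slow, fast) diffusivities in um^2/ms.
#' @param t2SlowGrid,t2FastGrid calibration grid in ms; ignored when
#'   \code{fixedT2} is given.
#' @param fixedT2 optional numeric length-2 (t2Slow, t2Fast) in ms.
#' @param models character subset of
#'   c("twoComponent", "biExponential", "mono").
#' @param poolMax maximum pooled training voxels for calibration; pools
#'   larger than this are subsampled (seeded). Subsampling changes the cost
#'   scale, not its minimizer, in expectation.
#' @param outDir optional output directory; when set, all tables, curves,
#'   the cost surface and QC summaries are written there.
#' @param alpha family-wise significance level before Bonferroni.
#' @param seed seed for the calibration-pool subsample.
#' @return a list of class \code{"pipelineConfig"}.
#' @examples
#' cfg <- pipelineConfig(cohortSpec(nTrain = 4, nTest = 4, nBph = 2,
#'                                  pzTrain = 3, pzTest = 3))
#' @export
pipelineConfig <- function(cohort = cohortSpec(),
                           adcPair = c(0.3, 2.6),
                           t2SlowGrid = defaultT2Grid()$t2Slow,
                           t2FastGrid = defaultT2Grid()$t2Fast,
                           fixedT2 = NULL,
                           models = c("twoComponent", "biExponential", "mono"),
                           poolMax = 20000, outDir = NULL,
                           alpha = 0.05, seed = 1) {
  stopifnot(inherits(cohort, "cohortSpec"))
  models <- match.arg(models, several.ok = TRUE)
  if (is.null(fixedT2) && (length(t2SlowGrid) < 1 || length(t2FastGrid) < 1))
    stop("either a calibration grid or a fixed T2 pair must be supplied")
  if (!is.null(fixedT2)) stopifnot(length(fixedT2) == 2,
                                   fixedT2[1] < fixedT2[2])
  structure(list(cohort = cohort, adcPair = adcPair,
                 t2SlowGrid = t2SlowGrid, t2FastGrid = t2FastGrid,
                 fixedT2 = fixedT2, models = models, poolMax = poolMax,
                 outDir = outDir, alpha = alpha, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param path JSON file path.
#' @return \code{readPipelineConfig} returns the restored
#'   \code{pipelineConfig}; the writer returns \code{path} invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "pipelineConfig"))
  co <- config$cohort
  ph <- co$phantom
  obj <- list(
    cohort = list(nTrain = co$nTrain, nTest = co$nTest, nBph = co$nBph,
                  pzTrain = co$pzTrain, pzTest = co$pzTest,
                  gradeNoiseSd = co$gradeNoiseSd, seed = co$seed),
    phantom = list(gridDim = ph$gridDim, voxelSize = ph$voxelSize,
                   classes = ph$classes,
                   echoTimes = echoTimes(ph$scheme),
                   bValues = bValues(ph$scheme),
                   basis = list(adcSlow = ph$basis@adcSlow,
                                adcFast = ph$basis@adcFast,
                                t2Slow = ph$basis@t2Slow,
                                t2Fast = ph$basis@t2Fast),
                   sigma = ph$sigma, targetSnr = ph$targetSnr,
                   si0SdLog = ph$si0SdLog),
    adcPair = config$adcPair, t2SlowGrid = config$t2SlowGrid,
    t2FastGrid = config$t2FastGrid, fixedT2 = config$fixedT2,
    models = config$models, poolMax = config$poolMax,
    outDir = config$outDir, alpha = config$alpha, seed = config$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- o$phantom$basis
  ph <- phantomSpec(
    gridDim = o$phantom$gridDim, voxelSize = o$phantom$voxelSize,
    classes = o$phantom$classes,
    scheme = AcquisitionScheme(o$phantom$echoTimes, o$phantom$bValues),
    basis = ComponentBasis(b$adcSlow, b$adcFast, b$t2Slow, b$t2Fast),
    sigma = o$phantom$sigma, targetSnr = o$phantom$targetSnr,
    si0SdLog = o$phantom$si0SdLog)
  co <- cohortSpec(o$cohort$nTrain, o$cohort$nTest, o$cohort$nBph,
                   o$cohort$pzTrain, o$cohort$pzTest, phantom = ph,
                   gradeNoiseSd = o$cohort$gradeNoiseSd,
                   seed = o$cohort$seed)
  pipelineConfig(co, adcPair = o$adcPair, t2SlowGrid = o$t2SlowGrid,
                 t2FastGrid = o$t2FastGrid, fixedT2 = o$fixedT2,
                 models = o$models, poolMax = o$poolMax,
                 outDir = o$outDir, alpha = o$alpha, seed = o$seed)
}

# pool kept training voxels into a nMeas x nVox matrix, subsampled to cap
.poolTrainingVoxels <- function(cohort, exclusions, cap, seed) {
  tab <- cohort$table
  idx <- which(tab$split == "train")
  pools <- lapply(idx, function(i) {
    vol <- cohort$patients[[i]]$volume
    keep <- which(as.vector(exclusions[[i]]$keep))
    d <- dim(volumeData(vol))
    S4 <- matrix(volumeData(vol), nrow = prod(d[1:3]), ncol = d[4])
    t(S4[keep, , drop = FALSE])
  })
  S <- do.call(cbind, pools)
  if (ncol(S) > cap) {
    set.seed(seed)
    S <- S[, sample.int(ncol(S), cap), drop = FALSE]
  }
  S
}

# gather voxel values of one metric for ROC: tumor ROI voxels vs all other
# valid voxels inside the box masks of cancer patients in the given split
.collectRocValues <- function(cohort, fits, split, model, metric) {
  tab <- cohort$table
  idx <- which(tab$split == split & tab$arm == "cancer")
  tumor <- numeric(); rest <- numeric()
  for (i in idx) {
    fm <- fits[[i]][[model]]
    ok <- validMask(fm)
    vals <- fitMap(fm, metric)
    tm <- cohort$patients[[i]]$truth$masks$tumor
    tumor <- c(tumor, vals[ok & tm])
    rest <- c(rest, vals[ok & !tm])
  }
  list(tumor = tumor, rest = rest)
}

#' Run the full analysis pipeline on a phantom cohort
#'
#' Steps: simulate the cohort; apply the exclusion rules per patient;
#' calibrate the population T2 pair by pooled grid search on the training
#' split (skipped when a fixed pair is configured); fit the requested
#' models per patient; summarize each region of interest; run the
#' statistical evaluation (paired PZ tumor-vs-normal tests on the test
#' set, unpaired non-PZ tumor-vs-BPH tests on all patients, Bonferroni
#' adjustment over all comparisons, voxel-wise ROC with training-derived
#' threshold transfer, Spearman correlation with grade on the test set).
#' Deterministic given the configuration.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print stage progress and counts.
#' @return list with \code{cohort} (metadata table), \code{calibration}
#'   (a \code{\link{CostSurface-class}} or NULL), \code{basis} (the
#'   calibrated ComponentBasis), \code{roiTable}, \code{stats} (rank tests
#'   + Spearman, long format), \code{diagnostics} (per-metric ROC summary:
#'   AUC, training threshold, test sensitivity/specificity, polarity),
#'   \code{rocCurves}, \code{qc} (exclusion summary), \code{alphaAdjusted}.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(cohortSpec(nTrain = 4, nTest = 4, nBph = 2,
#'                                  pzTrain = 3, pzTest = 3, seed = 1),
#'                       fixedT2 = c(45, 180))
#' res <- runPipeline(cfg)
#' res$diagnostics
#' }
#' @export
runPipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating cohort (%d patients)...",
      config$cohort$nTrain + config$cohort$nTest + config$cohort$nBph)
  cohort <- simulateCohort(config$cohort)
  tab <- cohort$table
  n <- nrow(tab)

  say("applying exclusion rules...")
  exclusions <- lapply(cohort$patients,
                       function(p) buildExclusionMask(p$volume))

  if (is.null(config$fixedT2)) {
    say("calibrating T2 pair on the training split...")
    S <- .poolTrainingVoxels(cohort, exclusions, config$poolMax, config$seed)
    surface <- calibrateT2(S, config$cohort$phantom$scheme,
                           adcPair = config$adcPair,
                           t2SlowGrid = config$t2SlowGrid,
                           t2FastGrid = config$t2FastGrid)
    t2 <- optimalT2(surface)
    say("  optimum: t2Slow = %g ms, t2Fast = %g ms", t2[1], t2[2])
  } else {
    surface <- NULL
    t2 <- c(t2Slow = config$fixedT2[1], t2Fast = config$fixedT2[2])
  }
  basis <- ComponentBasis(config$adcPair[1], config$adcPair[2],
                          t2[["t2Slow"]], t2[["t2Fast"]])

  say("fitting %s...", paste(config$models, collapse = ", "))
  fits <- vector("list", n)
  for (i in seq_len(n)) {
    vol <- cohort$patients[[i]]$volume
    fits[[i]] <- setNames(lapply(config$models, function(mdl)
      fitVolume(vol, mdl, basis, exclusion = exclusions[[i]])),
      config$models)
  }

  say("summarizing regions of interest...")
  roiRows <- list()
  for (i in seq_len(n)) {
    masks <- cohort$patients[[i]]$truth$masks
    meta <- tab[i, ]
    for (roi in c("tumor", "normal", "bph")) {
      if (!any(masks[[roi]])) next
      row <- roiSummary(fits[[i]], masks[[roi]], roi)
      row <- cbind(meta[, c("patient", "arm", "split", "zone", "ggg")], row)
      roiRows[[length(roiRows) + 1]] <- row
    }
  }
  roiTable <- do.call(rbind, roiRows)
  rownames(roiTable) <- NULL

  metricCols <- c(twoComponent = "sfTwoComponent",
                  biExponential = "sfBiExponential", mono = "adcMono")
  metricCols <- metricCols[config$models]
  polarity <- c(twoComponent = "higher", biExponential = "higher",
                mono = "lower")

  say("rank tests and correlations...")
  statRows <- list()
  pzTest <- roiTable[roiTable$split == "test" & roiTable$zone == "PZ", ]
  nonPz <- roiTable[roiTable$zone == "nonPZ", ]
  for (mdl in config$models) {
    col <- metricCols[[mdl]]
    tu <- pzTest[pzTest$roi == "tumor", ]
    no <- pzTest[pzTest$roi == "normal", ]
    common <- intersect(tu$patient, no$patient)
    p1 <- pairedTest(tu[[col]][match(common, tu$patient)],
                     no[[col]][match(common, no$patient)])
    statRows[[length(statRows) + 1]] <- data.frame(
      comparison = "pz_tumor_vs_normal", test = "wilcoxon_signed_rank",
      metric = col, n = length(common), statistic = NA_real_, p = p1)
    tuN <- nonPz[nonPz$roi == "tumor", ]
    bph <- nonPz[nonPz$roi == "bph", ]
    p2 <- unpairedTest(tuN[[col]], bph[[col]])
    statRows[[length(statRows) + 1]] <- data.frame(
      comparison = "nonpz_tumor_vs_bph", test = "mann_whitney_u",
      metric = col, n = nrow(tuN) + nrow(bph), statistic = NA_real_, p = p2)
    tumorsTest <- roiTable[roiTable$split == "test" & roiTable$roi == "tumor", ]
    sp <- spearmanGradeCorrelation(tumorsTest[[col]], tumorsTest$ggg)
    statRows[[length(statRows) + 1]] <- data.frame(
      comparison = "tumor_mean_vs_ggg", test = "spearman",
      metric = col, n = nrow(tumorsTest), statistic = sp$rho, p = sp$p)
  }
  stats <- do.call(rbind, statRows)
  alphaAdj <- adjustedAlpha(config$alpha, nrow(stats))

  say("voxel-wise ROC with threshold transfer...")
  diagRows <- list(); curves <- list()
  metrics <- c(twoComponent = "sfSlow", biExponential = "sfSlow",
               mono = "adc")
  for (mdl in config$models) {
    tr <- .collectRocValues(cohort, fits, "train", mdl, metrics[[mdl]])
    te <- .collectRocValues(cohort, fits, "test", mdl, metrics[[mdl]])
    dg <- thresholdTransfer(tr$tumor, tr$rest, te$tumor, te$rest,
                            polarity[[mdl]])
    diagRows[[length(diagRows) + 1]] <- data.frame(
      metric = metricCols[[mdl]], auc = dg$auc, threshold = dg$threshold,
      sensitivity = dg$sensitivity, specificity = dg$specificity,
      polarity = dg$polarity,
      nTumorVoxels = length(te$tumor), nNonTumorVoxels = length(te$rest))
    curve <- rocAnalysis(te$tumor, te$rest, polarity[[mdl]])$curve
    curve$metric <- metricCols[[mdl]]
    curves[[length(curves) + 1]] <- curve
  }
  diagnostics <- do.call(rbind, diagRows)
  rocCurves <- do.call(rbind, curves)

  qcAll <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(patient = tab$patient[i],
          as.data.frame(exclusions[[i]]$qc))))
  # excluded fraction restricted to tissue (tumor/normal/bph) regions
  tissueExcl <- vapply(seq_len(n), function(i) {
    masks <- cohort$patients[[i]]$truth$masks
    tissue <- masks$tumor | masks$normal | masks$bph
    c(sum(tissue & !exclusions[[i]]$keep), sum(tissue))
  }, numeric(2))
  qcSummary <- list(
    boxExcludedFraction = sum(qcAll$nExcluded) / sum(qcAll$nBox),
    tissueExcludedFraction = sum(tissueExcl[1, ]) / sum(tissueExcl[2, ]))

  res <- list(cohort = tab, calibration = surface, basis = basis,
              roiTable = roiTable, stats = stats,
              diagnostics = diagnostics, rocCurves = rocCurves,
              qc = qcAll, qcSummary = qcSummary, alphaAdjusted = alphaAdj,
              config = config)

  if (!is.null(config$outDir)) {
    od <- config$outDir
    if (!dir.exists(od)) dir.create(od, recursive = TRUE)
    utils::write.csv(roiTable, file.path(od, "roi_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(stats, file.path(od, "statistics.csv"),
                     row.names = FALSE)
    utils::write.csv(diagnostics, file.path(od, "diagnostics.csv"),
                     row.names = FALSE)
    utils::write.csv(rocCurves, file.path(od, "roc_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(qcAll, file.path(od, "qc.csv"), row.names = FALSE)
    if (!is.null(surface)) {
      utils::write.csv(costSurfaceTable(surface),
                       file.path(od, "cost_surface.csv"), row.names = FALSE)
      jsonlite::write_json(as.list(optimalT2(surface)),
                           file.path(od, "calibration.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(qcSummary, file.path(od, "qc_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writePipelineConfig(config, file.path(od, "config.json"))
  }
  res
}
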