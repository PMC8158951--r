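# NIfTI-1 ingestion and export. Voxel indexing is 0-based on disk (NIfTI
# convention, affines carry world coordinates) and 1-based in R arrays;
# masks are stored as uint8 {0,1}.

#' Read a co-registered acquisition into a SignalVolume
#'
#' Reads one single-measurement NIfTI file per (TE, b) combination, checks
#' that every grid (and every mask) agrees in shape and affine, and orders
#' the measurement axis canonically by (TE, then b). Inputs are assumed
#' already co-registered.
#'
#' @param paths character vector of NIfTI file paths, one per measurement.
#' @param te,b numeric vectors parallel to \code{paths}: the TE (ms) and
#'   b-value (s/mm^2) of each file.
#' @param boxMaskPath,backgroundMaskPath NIfTI masks (uint8 {0,1}) on the
#'   same grid; the box mask defaults to the full grid, the background mask
#'   must be supplied for exclusion-rule processing.
#' @return a \code{\link{SignalVolume-class}} object.
#' @export
readAcquisition <- function(paths, te, b, boxMaskPath = NULL,
                            backgroundMaskPath = NULL) {
  stopifnot(length(paths) == length(te), length(te) == length(b))
  scheme <- AcquisitionScheme(unique(te), unique(b))
  m <- measurementTable(scheme)
  if (nrow(m) != length(paths))
    stop("paths must cover the full TE x b cross product exactly once")
  imgs <- lapply(paths, RNifti::readNifti)
  d <- dim(imgs[[1]])
  aff <- RNifti::xform(imgs[[1]])
  for (i in seq_along(imgs)) {
    if (!identical(dim(imgs[[i]]), d))
      stop("grid mismatch in '", paths[i], "'")
    if (max(abs(RNifti::xform(imgs[[i]]) - aff)) > 1e-4)
      stop("affine mismatch in '", paths[i], "'")
  }
  ord <- order(te, b)
  dat <- array(0, dim = c(d, nrow(m)))
  for (k in seq_len(nrow(m))) dat[, , , k] <- imgs[[ord[k]]]

  readMask <- function(path) {
    if (is.null(path)) return(NULL)
    img <- RNifti::readNifti(path)
    if (!identical(dim(img), d))
      stop("mask grid mismatch in '", path, "'")
    array(img > 0, dim = d)
  }
  pix <- RNifti::pixdim(imgs[[1]])[1:3]
  vol <- SignalVolume(dat, scheme, voxelSize = pix,
                      boxMask = readMask(boxMaskPath),
                      backgroundMask = if (is.null(backgroundMaskPath))
                        array(FALSE, d) else readMask(backgroundMaskPath))
  attr(vol@data, "template") <- imgs[[1]]
  vol
}

#' Write fitted parameter maps as NIfTI plus a QC report
#'
#' One NIfTI file per map (\code{si0}, \code{sfSlow} or \code{adc},
#' \code{rmse}) plus \code{valid} as uint8, with the affine copied from the
#' template image when given; the QC counts go to \code{qc.json}.
#'
#' @param fitMaps a \code{\link{FitMaps-class}} object.
#' @param dir output directory (created if missing).
#' @param template optional NIfTI image (or the SignalVolume read by
#'   \code{\link{readAcquisition}}) supplying the affine.
#' @param prefix filename prefix, default the model name.
#' @return invisibly, the written file paths.
#' @export
writeMaps <- function(fitMaps, dir, template = NULL, prefix = NULL) {
  stopifnot(is(fitMaps, "FitMaps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- modelName(fitMaps)
  if (is(template, "SignalVolume"))
    template <- attr(template@data, "template")
  files <- character()
  for (nm in names(fitMaps@maps)) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, nm))
    img <- fitMaps@maps[[nm]]
    if (!is.null(template))
      img <- RNifti::asNifti(img, reference = template)
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  f <- file.path(dir, sprintf("%s_valid.nii.gz", prefix))
  vimg <- array(as.integer(validMask(fitMaps)), dim(validMask(fitMaps)))
  if (!is.null(template)) vimg <- RNifti::asNifti(vimg, reference = template)
  RNifti::writeNifti(vimg, f, datatype = "uint8")
  files <- c(files, f)
  qf <- file.path(dir, sprintf("%s_qc.json", prefix))
  jsonlite::write_json(qcReport(fitMaps), qf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, qf))
}

#' Write a SignalVolume to disk
#'
#' The 4D data as one NIfTI, the masks as uint8 NIfTI on the same grid,
#' and the scheme as JSON.
#'
#' @param volume a \code{\link{SignalVolume-class}} object.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return invisibly, the written file paths.
#' @export
writeSignalVolume <- function(volume, dir, prefix = "acq") {
  stopifnot(is(volume, "SignalVolume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dataF <- file.path(dir, paste0(prefix, "_data.nii.gz"))
  RNifti::writeNifti(volumeData(volume), dataF)
  boxF <- file.path(dir, paste0(prefix, "_boxmask.nii.gz"))
  bgF <- file.path(dir, paste0(prefix, "_backgroundmask.nii.gz"))
  RNifti::writeNifti(array(as.integer(boxMask(volume)),
                           dim(boxMask(volume))), boxF, datatype = "uint8")
  RNifti::writeNifti(array(as.integer(backgroundMask(volume)),
                           dim(backgroundMask(volume))), bgF,
                     datatype = "uint8")
  schF <- file.path(dir, paste0(prefix, "_scheme.json"))
  jsonlite::write_json(measurementTable(volume@scheme), schF, digits = NA)
  invisible(c(dataF, boxF, bgF, schF))
}
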