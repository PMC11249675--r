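#' @include AllClasses.R AllGenerics.R
NULL

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, record) {
  jsonlite::write_json(record, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a frame stack as a multi-page TIFF
#'
#' Frames are stored grayscale, page order = time order. Integer counts
#' in `[0, 65535]` are stored as 16-bit unsigned samples (lossless);
#' non-integer data fall back to 32-bit float samples normalized to the
#' recorded range. A JSON sidecar (`<path>.json`) carries the pixel
#' size, exposure, storage format, and the full provenance metadata, so
#' a write-then-read round-trip reproduces the stack bit for bit.
#'
#' When the sidecar is absent (a foreign TIFF), 16-bit storage with a
#' 46 nm pixel and 1 ms exposure is assumed.
#'
#' @param stack a [FrameStack-class]
#' @param path TIFF file path
#' @return `writeStack` returns `path` invisibly; `readStack` returns a
#'   [FrameStack-class]
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  fr <- stack@frames
  d <- dim(fr)
  isInt <- all(fr >= 0) && all(fr <= 65535) && all(fr == round(fr))
  pages <- lapply(seq_len(d[3L]), function(t) fr[, , t, drop = TRUE])
  if (isInt) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L)
    fmt <- list(format = "uint16", scale_min = 0, scale_max = 65535)
  } else {
    lo <- min(fr)
    hi <- max(fr)
    if (hi == lo) hi <- lo + 1
    tiff::writeTIFF(lapply(pages, function(p) (p - lo) / (hi - lo)), path,
                    bits.per.sample = 32L)
    fmt <- list(format = "float32", scale_min = lo, scale_max = hi)
  }
  .writeSidecar(path, c(list(type = "FrameStack",
                             pixel_size_nm = stack@pixelSizeNm,
                             exposure_ms = stack@exposureMs,
                             n_frames = d[3L], shape = d[1:2]),
                        fmt, list(metadata = stack@metadata)))
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      stop("malformed TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(shapes != shapes[, 1]))
    stop("inconsistent page shapes in ", path)
  sc <- .readSidecar(path)
  lo <- if (is.null(sc)) 0 else sc$scale_min
  hi <- if (is.null(sc)) 65535 else sc$scale_max
  fmt <- if (is.null(sc)) "uint16" else sc$format
  fr <- array(0, dim = c(shapes[, 1], length(pages)))
  for (t in seq_along(pages)) {
    v <- pages[[t]] * (hi - lo) + lo
    if (fmt == "uint16") v <- round(v)
    fr[, , t] <- v
  }
  new("FrameStack", frames = fr,
      pixelSizeNm = if (is.null(sc)) 46 else sc$pixel_size_nm,
      exposureMs = if (is.null(sc)) 1 else sc$exposure_ms,
      metadata = if (is.null(sc) || is.null(sc$metadata)) list() else
        as.list(sc$metadata))
}

#' Write / read a cumulant image as 32-bit float TIFF
#'
#' Cumulant values (which can be negative for order 3) are stored as
#' 32-bit float samples normalized to the image range; the range, the
#' cumulant order/lag and the provenance metadata live in the JSON
#' sidecar, so reading restores the values to within float32 precision.
#'
#' @param ci a [CumulantImage-class]
#' @param path TIFF file path
#' @return `writeCumulantImage` returns `path` invisibly;
#'   `readCumulantImage` returns a [CumulantImage-class]
#' @export
writeCumulantImage <- function(ci, path) {
  stopifnot(is(ci, "CumulantImage"))
  lo <- min(ci@image)
  hi <- max(ci@image)
  if (hi == lo) hi <- lo + 1
  tiff::writeTIFF((ci@image - lo) / (hi - lo), path, bits.per.sample = 32L)
  .writeSidecar(path, list(type = "CumulantImage", order = ci@order,
                           lag = ci@lag, n_frames_used = ci@nFramesUsed,
                           format = "float32", scale_min = lo,
                           scale_max = hi, metadata = ci@metadata))
  invisible(path)
}

#' @rdname writeCumulantImage
#' @export
readCumulantImage <- function(path) {
  sc <- .readSidecar(path)
  if (is.null(sc) || !identical(sc$type, "CumulantImage"))
    stop("no CumulantImage sidecar for ", path)
  img <- tiff::readTIFF(path) * (sc$scale_max - sc$scale_min) + sc$scale_min
  new("CumulantImage", order = as.integer(sc$order),
      lag = as.integer(sc$lag), image = img,
      nFramesUsed = as.integer(sc$n_frames_used),
      metadata = if (is.null(sc$metadata)) list() else as.list(sc$metadata))
}

#' Write / read a z-scan series as TIFFs plus an index file
#'
#' One multi-page TIFF per defocus (`z000.tif`, `z001.tif`, ...) and an
#' `index.csv` with columns `z_um, filename`.
#'
#' @param series a [ZScanSeries-class]
#' @param dir directory to create/populate
#' @return `writeZScan` returns `dir` invisibly; `readZScan` returns a
#'   [ZScanSeries-class]
#' @export
writeZScan <- function(series, dir) {
  stopifnot(is(series, "ZScanSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- sprintf("z%03d.tif", seq_along(series@zUm) - 1L)
  for (i in seq_along(fn))
    writeStack(series@stacks[[i]], file.path(dir, fn[i]))
  utils::write.csv(data.frame(z_um = series@zUm, filename = fn),
                   file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname writeZScan
#' @export
readZScan <- function(dir) {
  idx <- file.path(dir, "index.csv")
  if (!file.exists(idx)) stop("no index.csv in ", dir)
  tab <- utils::read.csv(idx, stringsAsFactors = FALSE)
  stacks <- lapply(tab$filename, function(f) readStack(file.path(dir, f)))
  zScanSeries(tab$z_um, stacks)
}

#' Write / read a sectioning curve as CSV
#'
#' Columns carry explicit units: `z_um, signal_mean, signal_std,
#' n_regions`.
#'
#' @param curve a [SectioningCurve-class]
#' @param path CSV file path
#' @return `writeSectioningCurve` returns `path` invisibly;
#'   `readSectioningCurve` returns a [SectioningCurve-class]
#' @export
writeSectioningCurve <- function(curve, path) {
  stopifnot(is(curve, "SectioningCurve"))
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSectioningCurve
#' @export
readSectioningCurve <- function(path) {
  tab <- utils::read.csv(path)
  new("SectioningCurve", zUm = tab$z_um, signal = tab$signal_mean,
      uncertainty = tab$signal_std, nRegions = as.integer(tab$n_regions[1]))
}

#' Write a curve fit as a structured JSON record
#'
#' @param fit a [CurveFit-class]
#' @param path JSON file path
#' @return `path`, invisibly
#' @export
writeFitRecord <- function(fit, path) {
  stopifnot(is(fit, "CurveFit"))
  jsonlite::write_json(
    list(model = fit@model, parameters = as.list(fit@parameters),
         uncertainties = as.list(fit@uncertainties),
         fwhm_um = fit@fwhmUm, residual_norm = fit@residualNorm,
         converged = fit@converged, status = fit@status),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write PSF statistics as a structured JSON record
#'
#' @param stats a [PsfStats-class]
#' @param path JSON file path
#' @return `path`, invisibly
#' @export
writePsfStats <- function(stats, path) {
  stopifnot(is(stats, "PsfStats"))
  jsonlite::write_json(
    list(fwhm_nm = stats@fwhmNm, mean_fwhm_nm = meanFwhm(stats),
         sd_fwhm_nm = sdFwhm(stats), n_emitters = nEmitters(stats),
         peak_row = stats@peakRow, peak_col = stats@peakCol,
         status = stats@status),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a fluctuation diagnostic report
#'
#' The per-pixel trend fractions go to CSV (`pixel_row, pixel_col,
#' trend_fraction`) and the global summary to JSON.
#'
#' @param report a [FluctuationReport-class]
#' @param csvPath per-pixel CSV path
#' @param summaryPath JSON summary path (`NULL` to skip)
#' @return `csvPath`, invisibly
#' @export
writeDiagnostic <- function(report, csvPath, summaryPath = NULL) {
  stopifnot(is(report, "FluctuationReport"))
  d <- dim(report@trendFraction)
  utils::write.csv(
    data.frame(pixel_row = rep(seq_len(d[1L]), times = d[2L]),
               pixel_col = rep(seq_len(d[2L]), each = d[1L]),
               trend_fraction = as.vector(report@trendFraction)),
    csvPath, row.names = FALSE)
  if (!is.null(summaryPath)) {
    jsonlite::write_json(
      list(median_trend_fraction = report@medianFraction,
           verdict = report@verdict, threshold = report@threshold,
           n_frames = report@nFrames),
      summaryPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(csvPath)
}
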