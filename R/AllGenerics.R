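#' @include AllClasses.R
NULL

#' Accessors for sofisect objects
#'
#' Small accessor generics used across the package: `frames()` returns
#' the raw frame array of a [FrameStack-class]; `nFrames()` the number of
#' frames; `pixelSize()` the sample-plane pixel size in nm; `exposure()`
#' the frame exposure in ms; `zPositions()` the defocus values (um) of an
#' [AcquisitionPlan-class] or [ZScanSeries-class]; `nEmitters()` the
#' number of emitters; `onFraction()` the stationary ON fraction of
#' [BlinkKinetics-class]; `cumulantOrder()` and `cumulantLag()` the
#' estimator settings of a [CumulantImage-class]; `fwhm()` the fitted
#' FWHM (um for [CurveFit-class]); `meanFwhm()`/`sdFwhm()` the
#' mean/standard deviation (nm) of per-emitter FWHMs in a
#' [PsfStats-class]; `verdict()` the global verdict of a
#' [FluctuationReport-class].
#'
#' @param x an object of the documented class
#' @return the accessed component (see Description)
#' @examples
#' onFraction(blinkKinetics(0.3, 0.1))
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("exposure", function(x) standardGeneric("exposure"))
#' @rdname accessors
#' @export
setGeneric("zPositions", function(x) standardGeneric("zPositions"))
#' @rdname accessors
#' @export
setGeneric("nEmitters", function(x) standardGeneric("nEmitters"))
#' @rdname accessors
#' @export
setGeneric("onFraction", function(x) standardGeneric("onFraction"))
#' @rdname accessors
#' @export
setGeneric("cumulantOrder", function(x) standardGeneric("cumulantOrder"))
#' @rdname accessors
#' @export
setGeneric("cumulantLag", function(x) standardGeneric("cumulantLag"))
#' @rdname accessors
#' @export
setGeneric("fwhm", function(x) standardGeneric("fwhm"))
#' @rdname accessors
#' @export
setGeneric("meanFwhm", function(x) standardGeneric("meanFwhm"))
#' @rdname accessors
#' @export
setGeneric("sdFwhm", function(x) standardGeneric("sdFwhm"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
setMethod("frames", "FrameStack", function(x) x@frames)
#' @rdname accessors
setMethod("nFrames", "FrameStack", function(x) dim(x@frames)[3L])
#' @rdname accessors
setMethod("nFrames", "AcquisitionPlan", function(x) x@nFrames)
#' @rdname accessors
setMethod("pixelSize", "FrameStack", function(x) x@pixelSizeNm)
#' @rdname accessors
setMethod("pixelSize", "AcquisitionPlan", function(x) x@pixelSizeNm)
#' @rdname accessors
setMethod("exposure", "FrameStack", function(x) x@exposureMs)
#' @rdname accessors
setMethod("exposure", "AcquisitionPlan", function(x) x@exposureMs)
#' @rdname accessors
setMethod("zPositions", "AcquisitionPlan", function(x) x@zPositionsUm)
#' @rdname accessors
setMethod("zPositions", "ZScanSeries", function(x) x@zUm)
#' @rdname accessors
setMethod("nEmitters", "EmitterSet", function(x) length(x@x))
#' @rdname accessors
setMethod("nEmitters", "PsfStats", function(x) length(x@fwhmNm))
#' @rdname accessors
setMethod("onFraction", "BlinkKinetics", function(x) {
  tot <- x@pOnToOff + x@pOffToOn
  if (tot == 0) return(NA_real_)  # degenerate frozen chain
  x@pOffToOn / tot
})
#' @rdname accessors
setMethod("cumulantOrder", "CumulantImage", function(x) x@order)
#' @rdname accessors
setMethod("cumulantLag", "CumulantImage", function(x) x@lag)
#' @rdname accessors
setMethod("fwhm", "CurveFit", function(x) x@fwhmUm)
#' @rdname accessors
setMethod("meanFwhm", "PsfStats", function(x) {
  if (length(x@fwhmNm) == 0L) NA_real_ else mean(x@fwhmNm)
})
#' @rdname accessors
setMethod("sdFwhm", "PsfStats", function(x) {
  if (length(x@fwhmNm) < 2L) NA_real_ else stats::sd(x@fwhmNm)
})
#' @rdname accessors
setMethod("verdict", "FluctuationReport", function(x) x@verdict)

#' @describeIn ZScanSeries-class number of defocus positions
#' @param x a `ZScanSeries`
#' @export
setMethod("length", "ZScanSeries", function(x) length(x@zUm))

#' @describeIn ZScanSeries-class extract the [FrameStack-class] at index `i`
#' @param i index of the defocus position
#' @export
setMethod("[[", "ZScanSeries", function(x, i) x@stacks[[i]])

#' @describeIn CumulantImage-class the cumulant image as a plain matrix
#' @export
setMethod("as.matrix", "CumulantImage", function(x, ...) x@image)

#' @describeIn SectioningCurve-class the curve as a data.frame with
#'   columns `z_um`, `signal_mean`, `signal_std`, `n_regions`
#' @param x a `SectioningCurve`
#' @param ... unused
#' @export
setMethod("as.data.frame", "SectioningCurve", function(x, ...) {
  data.frame(z_um = x@zUm, signal_mean = x@signal,
             signal_std = x@uncertainty, n_regions = x@nRegions)
})

setMethod("show", "OpticalConfig", function(object) {
  cat("OpticalConfig\n")
  cat(sprintf("  NA %.2f, n %.3f | exc %g nm, em %g nm\n",
              object@numericalAperture, object@refractiveIndex,
              object@excitationWavelengthNm, object@emissionWavelengthNm))
  cat(sprintf("  f_tube %g mm, f_obj %g mm, beam %g mm, pixel %g nm\n",
              object@tubeFocalLengthMm, object@objectiveFocalLengthMm,
              object@beamDiameterAtGratingMm, object@pixelSizeSampleNm))
})

setMethod("show", "TFSectioningModel", function(object) {
  fw <- if (object@a > 0) sprintf("%.3f um", 2 / sqrt(object@a)) else "Inf (wide-field limit)"
  cat(sprintf("TFSectioningModel: a %.4g /um^2 (FWHM %s), z0 %.3g um, amplitude %.4g, offset %.4g\n",
              object@a, fw, object@z0, object@amplitude, object@offset))
})

setMethod("show", "Psf3D", function(object) {
  cat(sprintf("Psf3D (separable Gaussian, %s): lateral FWHM %.1f nm, axial FWHM %.1f nm\n",
              object@normalization, object@lateralFwhmNm, object@axialFwhmNm))
})

setMethod("show", "EmitterSet", function(object) {
  n <- length(object@x)
  cat(sprintf("EmitterSet: %d emitter%s", n, if (n == 1) "" else "s"))
  if (n) {
    cat(sprintf(", z in [%.3g, %.3g] um, brightness %.4g-%.4g photons/frame",
                min(object@z), max(object@z),
                min(object@brightness), max(object@brightness)))
  }
  cat("\n")
})

setMethod("show", "BlinkKinetics", function(object) {
  cat(sprintf("BlinkKinetics: p(ON->OFF) %.3g, p(OFF->ON) %.3g, stationary ON fraction %.3g\n",
              object@pOnToOff, object@pOffToOn, onFraction(object)))
})

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FrameStack: %d x %d pixels x %d frames, %g nm/pixel, %g ms exposure\n",
              d[1], d[2], d[3], object@pixelSizeNm, object@exposureMs))
  if (!is.null(object@metadata$defocusUm))
    cat(sprintf("  defocus %g um\n", object@metadata$defocusUm))
})

setMethod("show", "ZScanSeries", function(object) {
  cat(sprintf("ZScanSeries: %d defocus positions, z %g .. %g um\n",
              length(object@zUm), min(object@zUm), max(object@zUm)))
})

setMethod("show", "CumulantImage", function(object) {
  cat(sprintf("CumulantImage: order %d, lag %d, %d x %d pixels, %d frames used\n",
              object@order, object@lag, nrow(object@image),
              ncol(object@image), object@nFramesUsed))
})

setMethod("show", "SectioningCurve", function(object) {
  cat(sprintf("SectioningCurve: %d z positions (%g .. %g um), %d summation regions\n",
              length(object@zUm), min(object@zUm), max(object@zUm),
              object@nRegions))
})

setMethod("show", "CurveFit", function(object) {
  cat(sprintf("CurveFit [%s]: %s\n", object@model,
              if (object@converged) "converged" else paste0("FAILED (", object@status, ")")))
  if (object@converged) {
    p <- object@parameters
    cat("  ", paste(sprintf("%s=%.5g", names(p), p), collapse = ", "), "\n")
    cat(sprintf("  FWHM %.4g um (+/- %.2g)\n", object@fwhmUm,
                object@uncertainties[["fwhm"]]))
  }
})

setMethod("show", "PsfStats", function(object) {
  n <- length(object@fwhmNm)
  if (n == 0L) {
    cat(sprintf("PsfStats: empty (%s)\n", object@status))
  } else {
    cat(sprintf("PsfStats: %d emitters, FWHM %.1f +/- %.1f nm\n",
                n, meanFwhm(object), if (n > 1) sdFwhm(object) else 0))
  }
})

setMethod("show", "FluctuationReport", function(object) {
  cat(sprintf("FluctuationReport: median trend fraction %.3f (threshold %.2f) -> %s\n",
              object@medianFraction, object@threshold, object@verdict))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat(sprintf("  excitation: %s | sample: %s | seed %d\n",
              object@excitationMode,
              if (is.null(object@sample$type)) "?" else object@sample$type,
              object@seed))
  cat(sprintf("  plan: %d frames x %d z positions, %d x %d pixels\n",
              object@plan@nFrames, length(object@plan@zPositionsUm),
              object@plan@frameShape[1], object@plan@frameShape[2]))
})
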