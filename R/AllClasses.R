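#' @import methods
NULL

.scalarOk <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Optical configuration of a temporal-focusing two-photon microscope
#'
#' Collects the geometric and spectral parameters of the excitation and
#' detection paths: objective numerical aperture and immersion index,
#' excitation/emission wavelengths, the tube-lens and objective focal
#' lengths forming the 4f telescope that images the grating onto the
#' sample, the excitation beam diameter at the grating, and the pixel
#' size back-projected to the sample plane.
#'
#' Lengths carry explicit units: wavelengths and pixel size in nm, lens
#' focal lengths and beam diameter in mm.
#'
#' @slot numericalAperture objective NA, dimensionless, in (0, 2]
#' @slot refractiveIndex immersion refractive index, >= 1
#' @slot excitationWavelengthNm central excitation wavelength, nm
#' @slot emissionWavelengthNm emission wavelength, nm
#' @slot tubeFocalLengthMm tube-lens focal length, mm
#' @slot objectiveFocalLengthMm objective focal length, mm
#' @slot beamDiameterAtGratingMm excitation beam diameter at the grating, mm
#' @slot pixelSizeSampleNm camera pixel size at the sample plane, nm
#'
#' @seealso [opticalConfig()] for the user-facing constructor
#' @export
setClass("OpticalConfig",
  representation(
    numericalAperture = "numeric",
    refractiveIndex = "numeric",
    excitationWavelengthNm = "numeric",
    emissionWavelengthNm = "numeric",
    tubeFocalLengthMm = "numeric",
    objectiveFocalLengthMm = "numeric",
    beamDiameterAtGratingMm = "numeric",
    pixelSizeSampleNm = "numeric"
  )
)

setValidity("OpticalConfig", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    if (!.scalarOk(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@numericalAperture <= 0 || object@numericalAperture > 2)
    msg <- c(msg, "numericalAperture must be in (0, 2]")
  if (object@refractiveIndex < 1)
    msg <- c(msg, "refractiveIndex must be >= 1")
  if (object@numericalAperture > object@refractiveIndex)
    msg <- c(msg, "numericalAperture cannot exceed refractiveIndex")
  lens <- c(
    object@excitationWavelengthNm, object@emissionWavelengthNm,
    object@tubeFocalLengthMm, object@objectiveFocalLengthMm,
    object@beamDiameterAtGratingMm, object@pixelSizeSampleNm
  )
  if (any(lens <= 0))
    msg <- c(msg, "all lengths must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' Axial response model of temporal-focusing two-photon excitation
#'
#' Parameters of the axial two-photon response
#' \deqn{F(z) = \mathrm{offset} + \mathrm{amplitude} / (1 + a (z - z_0)^2),}
#' a Lorentzian-form sectioning curve. The sectioning parameter `a`
#' (1/um^2) sets the axial confinement: the full width at half maximum of
#' the normalized response is `2/sqrt(a)`. `z0` (um) is the axial position
#' of the temporal focus, where the pulse is shortest and the two-photon
#' signal peaks. `a = 0` denotes the wide-field, no-sectioning limit.
#' The additive offset is used when fitting measured curves and defaults
#' to 0 for simulation.
#'
#' @slot a sectioning parameter, 1/um^2, >= 0
#' @slot z0 axial position of the temporal focus, um
#' @slot amplitude peak signal above offset, arbitrary signal units, >= 0
#' @slot offset additive baseline, signal units, >= 0
#'
#' @seealso [tfSectioningModel()], [tfAxialProfile()],
#'   [fwhmFromSectioningParameter()]
#' @export
setClass("TFSectioningModel",
  representation(a = "numeric", z0 = "numeric", amplitude = "numeric",
                 offset = "numeric"),
  prototype(a = 0.666, z0 = 0, amplitude = 1, offset = 0)
)

setValidity("TFSectioningModel", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    if (!.scalarOk(slot(object, s)))
      msg <- c(msg, sprintf("'%s' must be a finite numeric scalar", s))
  }
  if (length(msg)) return(msg)
  if (object@a < 0) msg <- c(msg, "a must be >= 0")
  if (object@amplitude < 0) msg <- c(msg, "amplitude must be >= 0")
  if (object@offset < 0) msg <- c(msg, "offset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Separable 3D Gaussian point spread function
#'
#' A detection PSF modeled as a separable Gaussian, the model under which
#' an order-N temporal cumulant shrinks the PSF by a factor sqrt(N).
#' Widths are stored as full widths at half maximum in nm;
#' `sigma = FWHM / (2 sqrt(2 ln 2))` per axis. Two normalizations are
#' supported: `"unit-peak"` (value 1 at the center) and `"unit-integral"`
#' (3D integral equal to 1, units 1/nm^3).
#'
#' @slot lateralFwhmNm lateral FWHM, nm
#' @slot axialFwhmNm axial FWHM, nm
#' @slot normalization `"unit-integral"` or `"unit-peak"`
#'
#' @seealso [gaussianPsf()], [psfValue()]
#' @export
setClass("Psf3D",
  representation(lateralFwhmNm = "numeric", axialFwhmNm = "numeric",
                 normalization = "character")
)

setValidity("Psf3D", function(object) {
  msg <- character()
  if (!.scalarOk(object@lateralFwhmNm) || object@lateralFwhmNm <= 0)
    msg <- c(msg, "lateralFwhmNm must be a positive scalar")
  if (!.scalarOk(object@axialFwhmNm) || object@axialFwhmNm <= 0)
    msg <- c(msg, "axialFwhmNm must be a positive scalar")
  if (!(length(object@normalization) == 1L &&
        object@normalization %in% c("unit-integral", "unit-peak")))
    msg <- c(msg, "normalization must be 'unit-integral' or 'unit-peak'")
  if (length(msg)) msg else TRUE
})

#' Point emitters with positions and brightness
#'
#' A set of independent point emitters (e.g. quantum dots). Coordinates
#' are continuous, in um, with the origin at the center of the imaged
#' field; `z` is the absolute axial position. `brightness` is the
#' expected number of detected photons per frame while the emitter is ON,
#' at the excitation maximum and in focus.
#'
#' @slot x,y lateral positions, um
#' @slot z axial positions, um
#' @slot brightness expected detected photons per frame when ON, >= 0
#'
#' @seealso [emitterSet()], [flatLayerSample()], [isolatedEmitterSample()]
#' @export
setClass("EmitterSet",
  representation(x = "numeric", y = "numeric", z = "numeric",
                 brightness = "numeric")
)

setValidity("EmitterSet", function(object) {
  n <- length(object@x)
  msg <- character()
  if (length(object@y) != n || length(object@z) != n ||
      length(object@brightness) != n)
    msg <- c(msg, "x, y, z and brightness must have equal length")
  if (any(!is.finite(c(object@x, object@y, object@z, object@brightness))))
    msg <- c(msg, "coordinates and brightness must be finite")
  if (length(msg) == 0L && any(object@brightness < 0))
    msg <- c(msg, "brightness must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Two-state Markov blinking kinetics
#'
#' Per-frame transition probabilities of a two-state (ON/OFF) Markov
#' chain describing emitter photoswitching. The stationary ON fraction is
#' `pOffToOn / (pOnToOff + pOffToOn)` when at least one probability is
#' positive. The frame exposure is assumed short relative to typical
#' dwell times, so states are constant within a frame.
#'
#' @slot pOnToOff per-frame ON to OFF transition probability, in [0,1]
#' @slot pOffToOn per-frame OFF to ON transition probability, in [0,1]
#'
#' @seealso [blinkKinetics()], [onFraction()], [simulateBlinkTraces()]
#' @export
setClass("BlinkKinetics",
  representation(pOnToOff = "numeric", pOffToOn = "numeric"),
  prototype(pOnToOff = 0.2, pOffToOn = 0.2)
)

setValidity("BlinkKinetics", function(object) {
  msg <- character()
  for (s in c("pOnToOff", "pOffToOn")) {
    p <- slot(object, s)
    if (!.scalarOk(p) || p < 0 || p > 1)
      msg <- c(msg, sprintf("'%s' must be a probability in [0,1]", s))
  }
  if (length(msg)) msg else TRUE
})

#' Camera model for a photon-number-resolving readout
#'
#' Detected photon expectations are converted to counts by Poisson shot
#' noise, an additive constant offset, Gaussian read noise, optional
#' integer quantization, and a clamp to `[0, maxCount]`. The default
#' `maxCount = 200` reflects a photon-number-resolving readout mode with
#' a 200-count dynamic range. `shotNoise = FALSE` disables the Poisson
#' draw (useful for noiseless forward-model checks).
#'
#' @slot readNoiseSd Gaussian read noise standard deviation, counts, >= 0
#' @slot offset constant camera offset, counts, in [0, maxCount)
#' @slot maxCount saturation clamp, counts
#' @slot quantize round counts to integers?
#' @slot shotNoise apply Poisson shot noise to the photon part?
#'
#' @seealso [cameraModel()], [renderFrame()]
#' @export
setClass("CameraModel",
  representation(readNoiseSd = "numeric", offset = "numeric",
                 maxCount = "numeric", quantize = "logical",
                 shotNoise = "logical"),
  prototype(readNoiseSd = 0.3, offset = 5, maxCount = 200,
            quantize = TRUE, shotNoise = TRUE)
)

setValidity("CameraModel", function(object) {
  msg <- character()
  if (!.scalarOk(object@readNoiseSd) || object@readNoiseSd < 0)
    msg <- c(msg, "readNoiseSd must be >= 0")
  if (!.scalarOk(object@offset) || !.scalarOk(object@maxCount))
    msg <- c(msg, "offset and maxCount must be numeric scalars")
  else if (object@offset < 0 || object@offset >= object@maxCount)
    msg <- c(msg, "offset must satisfy 0 <= offset < maxCount")
  if (length(object@quantize) != 1L || is.na(object@quantize))
    msg <- c(msg, "quantize must be TRUE or FALSE")
  if (length(object@shotNoise) != 1L || is.na(object@shotNoise))
    msg <- c(msg, "shotNoise must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Acquisition plan for a movie or a z-scan
#'
#' Describes how frames are recorded: the number of frames per axial
#' position, the exposure per frame, the frame geometry, and the ordered
#' defocus positions of a z-scan. The default emulates recording 300
#' frames of 1 ms exposure per axial position.
#'
#' @slot nFrames frames per z position, integer >= 2
#' @slot exposureMs exposure per frame, ms
#' @slot frameShape integer (rows, cols) of a frame
#' @slot pixelSizeNm pixel size at the sample, nm
#' @slot zPositionsUm strictly increasing defocus values, um
#' @slot seed master random seed for the acquisition
#'
#' @seealso [acquisitionPlan()], [simulateMovie()], [simulateZScan()]
#' @export
setClass("AcquisitionPlan",
  representation(nFrames = "integer", exposureMs = "numeric",
                 frameShape = "integer", pixelSizeNm = "numeric",
                 zPositionsUm = "numeric", seed = "integer"),
  prototype(nFrames = 300L, exposureMs = 1, frameShape = c(64L, 64L),
            pixelSizeNm = 46, zPositionsUm = 0, seed = 1L)
)

setValidity("AcquisitionPlan", function(object) {
  msg <- character()
  if (length(object@nFrames) != 1L || is.na(object@nFrames) ||
      object@nFrames < 2L)
    msg <- c(msg, "nFrames must be an integer >= 2 (cumulants need >= 2 frames)")
  if (!.scalarOk(object@exposureMs) || object@exposureMs <= 0)
    msg <- c(msg, "exposureMs must be > 0")
  if (length(object@frameShape) != 2L || any(object@frameShape < 1L))
    msg <- c(msg, "frameShape must be two positive integers (rows, cols)")
  if (!.scalarOk(object@pixelSizeNm) || object@pixelSizeNm <= 0)
    msg <- c(msg, "pixelSizeNm must be > 0")
  if (length(object@zPositionsUm) < 1L ||
      any(!is.finite(object@zPositionsUm)))
    msg <- c(msg, "zPositionsUm must be nonempty and finite")
  else if (length(object@zPositionsUm) > 1L &&
           any(diff(object@zPositionsUm) <= 0))
    msg <- c(msg, "zPositionsUm must be strictly increasing")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' A time-ordered stack of camera frames
#'
#' A movie recorded at one defocus position: a `rows x cols x time` array
#' of camera counts plus the acquisition metadata needed to interpret it
#' (pixel size, exposure, and a provenance record echoing the simulation
#' or file source).
#'
#' @slot frames numeric array, dim (rows, cols, nFrames)
#' @slot pixelSizeNm pixel size at the sample, nm
#' @slot exposureMs exposure per frame, ms
#' @slot metadata named list provenance record
#'
#' @seealso [frameStack()], [simulateMovie()], [readStack()], [writeStack()]
#' @export
setClass("FrameStack",
  representation(frames = "array", pixelSizeNm = "numeric",
                 exposureMs = "numeric", metadata = "list")
)

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3D array (rows, cols, time)")
  if (!.scalarOk(object@pixelSizeNm) || object@pixelSizeNm <= 0)
    msg <- c(msg, "pixelSizeNm must be > 0")
  if (!.scalarOk(object@exposureMs) || object@exposureMs <= 0)
    msg <- c(msg, "exposureMs must be > 0")
  if (length(msg)) msg else TRUE
})

#' A defocus-indexed series of frame stacks
#'
#' One [FrameStack-class] per defocus position, with strictly increasing
#' defocus values and shared acquisition parameters, as produced by
#' scanning a sample through the focus.
#'
#' @slot zUm strictly increasing defocus values, um
#' @slot stacks list of [FrameStack-class], same length as `zUm`
#'
#' @seealso [zScanSeries()], [simulateZScan()], [sofiZStack()]
#' @export
setClass("ZScanSeries",
  representation(zUm = "numeric", stacks = "list")
)

setValidity("ZScanSeries", function(object) {
  msg <- character()
  if (length(object@zUm) != length(object@stacks))
    msg <- c(msg, "zUm and stacks must have equal length")
  if (length(object@zUm) > 1L && any(diff(object@zUm) <= 0))
    msg <- c(msg, "zUm must be strictly increasing")
  if (!all(vapply(object@stacks, is, logical(1), "FrameStack")))
    msg <- c(msg, "stacks must all be FrameStack objects")
  if (length(msg) == 0L && length(object@stacks) > 1L) {
    shp <- vapply(object@stacks, function(s) dim(s@frames)[1:2], integer(2))
    if (any(shp != shp[, 1]))
      msg <- c(msg, "all stacks must share one frame shape")
  }
  if (length(msg)) msg else TRUE
})

#' A per-pixel temporal cumulant image (the SOFI signal)
#'
#' The order-2 or order-3 temporal cumulant of a movie, computed per
#' pixel. Order 2 at lag 0 is the unbiased sample variance; at lag tau >
#' 0 the sample autocovariance; order 3 is the unbiased third
#' k-statistic. Values carry units of (counts)^order and may be negative
#' for order 3.
#'
#' @slot order cumulant order, 2 or 3
#' @slot lag frame lag, integer >= 0 (order 3 supports lag 0 only)
#' @slot image numeric matrix of the frame shape
#' @slot nFramesUsed number of frames the estimate used
#' @slot metadata named list (estimator convention, provenance)
#'
#' @seealso [cumulant2()], [cumulant3()], [sofiZStack()]
#' @export
setClass("CumulantImage",
  representation(order = "integer", lag = "integer", image = "matrix",
                 nFramesUsed = "integer", metadata = "list")
)

setValidity("CumulantImage", function(object) {
  msg <- character()
  if (!(length(object@order) == 1L && object@order %in% c(2L, 3L)))
    msg <- c(msg, "order must be 2 or 3")
  if (length(object@lag) != 1L || is.na(object@lag) || object@lag < 0L)
    msg <- c(msg, "lag must be an integer >= 0")
  if (!is.numeric(object@image))
    msg <- c(msg, "image must be a numeric matrix")
  if (length(msg)) msg else TRUE
})

#' Summed signal versus defocus with region-based uncertainty
#'
#' For each defocus, the imaged field is partitioned into equal
#' rectangular regions, the signal is summed within each region, and the
#' curve records the mean across regions with the standard deviation
#' across regions as the per-point uncertainty.
#'
#' @slot zUm strictly increasing defocus values, um
#' @slot signal mean summed signal per defocus
#' @slot uncertainty standard deviation across regions per defocus, >= 0
#' @slot nRegions number of summation regions
#'
#' @seealso [summedSignalCurve()], [fitTfSectioning()],
#'   [fitGaussianSectioning()]
#' @export
setClass("SectioningCurve",
  representation(zUm = "numeric", signal = "numeric",
                 uncertainty = "numeric", nRegions = "integer")
)

setValidity("SectioningCurve", function(object) {
  msg <- character()
  n <- length(object@zUm)
  if (length(object@signal) != n || length(object@uncertainty) != n)
    msg <- c(msg, "zUm, signal and uncertainty must have equal length")
  if (n > 1L && any(diff(object@zUm) <= 0))
    msg <- c(msg, "zUm must be strictly increasing")
  if (length(msg) == 0L && any(object@uncertainty < 0))
    msg <- c(msg, "uncertainty must be >= 0")
  if (length(object@nRegions) != 1L || object@nRegions < 1L)
    msg <- c(msg, "nRegions must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' A fitted axial response curve
#'
#' Result of fitting a [SectioningCurve-class] with either the
#' Lorentzian-form axial response `offset + amplitude/(1 + a (z-z0)^2)`
#' (model `"eq1_lorentzian_form"`, FWHM `2/sqrt(a)`) or a Gaussian with
#' offset (model `"gaussian"`, FWHM `2 sqrt(2 ln 2) sigma`). When the fit
#' fails to converge, `converged` is `FALSE`, `fwhmUm` is `NA`, and
#' `status` carries the optimizer diagnostics.
#'
#' @slot model `"eq1_lorentzian_form"` or `"gaussian"`
#' @slot parameters named numeric (amplitude, z0, width parameter, offset)
#' @slot uncertainties named numeric standard errors (incl. `fwhm`)
#' @slot fwhmUm fitted FWHM, um (NA if not converged)
#' @slot residualNorm unweighted residual 2-norm
#' @slot converged did the optimizer converge?
#' @slot status human-readable fit diagnostics
#'
#' @seealso [fitTfSectioning()], [fitGaussianSectioning()]
#' @export
setClass("CurveFit",
  representation(model = "character", parameters = "numeric",
                 uncertainties = "numeric", fwhmUm = "numeric",
                 residualNorm = "numeric", converged = "logical",
                 status = "character")
)

setValidity("CurveFit", function(object) {
  msg <- character()
  if (!(length(object@model) == 1L &&
        object@model %in% c("eq1_lorentzian_form", "gaussian")))
    msg <- c(msg, "model must be 'eq1_lorentzian_form' or 'gaussian'")
  if (length(object@fwhmUm) != 1L)
    msg <- c(msg, "fwhmUm must be a single value")
  else if (isTRUE(object@converged) &&
           (!is.finite(object@fwhmUm) || object@fwhmUm <= 0))
    msg <- c(msg, "a converged fit must have a positive finite fwhmUm")
  if (length(msg)) msg else TRUE
})

#' Per-emitter PSF FWHM statistics
#'
#' Lateral FWHMs fitted to individual emitter images, reported with the
#' mean +/- standard deviation convention. May be empty when no
#' qualifying peak was found (`status` then says why).
#'
#' @slot fwhmNm fitted per-emitter lateral FWHMs, nm
#' @slot peakRow,peakCol 1-based pixel indices of the accepted peaks
#' @slot status `"ok"` or a reason for an empty result
#'
#' @seealso [estimatePsfFwhm()], [resolutionImprovement()]
#' @export
setClass("PsfStats",
  representation(fwhmNm = "numeric", peakRow = "integer",
                 peakCol = "integer", status = "character")
)

setValidity("PsfStats", function(object) {
  msg <- character()
  if (length(object@peakRow) != length(object@fwhmNm) ||
      length(object@peakCol) != length(object@fwhmNm))
    msg <- c(msg, "peakRow/peakCol must match fwhmNm in length")
  if (length(object@fwhmNm) && any(object@fwhmNm <= 0))
    msg <- c(msg, "fwhmNm must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-pixel fluctuation-versus-trend diagnostic report
#'
#' For each pixel the fraction of temporal variance explained by a linear
#' trend; the global verdict is `"fluctuation-dominated"` when the median
#' fraction over the assessed pixels is below the threshold, otherwise
#' `"trend-dominated"` (indicating bleaching or drift rather than optical
#' fluctuations).
#'
#' @slot trendFraction matrix of per-pixel variance fractions in [0,1]
#' @slot medianFraction median fraction over assessed pixels
#' @slot verdict `"fluctuation-dominated"` or `"trend-dominated"`
#' @slot threshold verdict threshold on the median fraction
#' @slot nFrames number of frames assessed
#'
#' @seealso [fluctuationDiagnostic()]
#' @export
setClass("FluctuationReport",
  representation(trendFraction = "matrix", medianFraction = "numeric",
                 verdict = "character", threshold = "numeric",
                 nFrames = "integer")
)

#' Complete configuration of a simulation-plus-analysis run
#'
#' Bundles everything a reproducible run needs: optics, detection PSF,
#' TF sectioning model, excitation mode, blinking kinetics, camera,
#' acquisition plan, sample specification, analysis options, and the
#' master seed. Round-trips losslessly through the YAML configuration
#' format (see [readRunConfig()]).
#'
#' @slot optics [OpticalConfig-class]
#' @slot psf [Psf3D-class] detection PSF
#' @slot sectioning [TFSectioningModel-class]
#' @slot excitationMode `"tf"` or `"widefield"`
#' @slot kinetics [BlinkKinetics-class]
#' @slot camera [CameraModel-class]
#' @slot plan [AcquisitionPlan-class]
#' @slot sample named list sample specification (see [buildSample()])
#' @slot analysis named list (order, lag, nRegions, fit model)
#' @slot seed master seed
#'
#' @seealso [readRunConfig()], [defaultRunConfig()], [sofisectCLI()]
#' @export
setClass("RunConfig",
  representation(optics = "OpticalConfig", psf = "Psf3D",
                 sectioning = "TFSectioningModel",
                 excitationMode = "character", kinetics = "BlinkKinetics",
                 camera = "CameraModel", plan = "AcquisitionPlan",
                 sample = "list", analysis = "list", seed = "integer")
)

setValidity("RunConfig", function(object) {
  if (!(length(object@excitationMode) == 1L &&
        object@excitationMode %in% c("tf", "widefield")))
    return("excitationMode must be 'tf' or 'widefield'")
  TRUE
})
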