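#' @include AllClasses.R AllGenerics.R
NULL

# FWHM of a Gaussian = 2 sqrt(2 ln 2) sigma
.FWHM_SIGMA <- 2 * sqrt(2 * log(2))

#' Convert between Gaussian FWHM and sigma
#'
#' @param fwhm full width at half maximum (any length unit)
#' @param sigma Gaussian standard deviation (same unit)
#' @return the corresponding sigma or FWHM
#' @examples
#' sigmaFromFwhm(274)           # ~116.4
#' fwhmFromSigma(sigmaFromFwhm(274))
#' @export
sigmaFromFwhm <- function(fwhm) fwhm / .FWHM_SIGMA

#' @rdname sigmaFromFwhm
#' @export
fwhmFromSigma <- function(sigma) sigma * .FWHM_SIGMA

#' Construct an optical configuration
#'
#' The objective focal length may be given directly or derived from the
#' nominal magnification via the manufacturer convention
#' `f_obj = 200 mm / magnification` (reference tube length 200 mm), e.g.
#' 2 mm for a 100x objective. Defaults describe a 1.4 NA oil-immersion
#' objective with 1030 nm excitation, 705 nm emission, a 400 mm tube
#' lens relaying an 8 mm excitation beam from the grating, and a 46 nm
#' sample-plane pixel.
#'
#' @param numericalAperture objective NA
#' @param refractiveIndex immersion index
#' @param excitationWavelengthNm central excitation wavelength, nm
#' @param emissionWavelengthNm emission wavelength, nm
#' @param tubeFocalLengthMm tube-lens focal length, mm
#' @param objectiveFocalLengthMm objective focal length, mm (overrides
#'   `magnification` when given)
#' @param magnification nominal objective magnification, used to derive
#'   the focal length when `objectiveFocalLengthMm` is `NULL`
#' @param beamDiameterAtGratingMm excitation beam diameter at the grating, mm
#' @param pixelSizeSampleNm camera pixel size at the sample plane, nm
#' @return an [OpticalConfig-class]
#' @examples
#' cfg <- opticalConfig()
#' excitationGeometry(cfg)  # demagnification 200, 40 um field
#' @export
opticalConfig <- function(numericalAperture = 1.4,
                          refractiveIndex = 1.515,
                          excitationWavelengthNm = 1030,
                          emissionWavelengthNm = 705,
                          tubeFocalLengthMm = 400,
                          objectiveFocalLengthMm = NULL,
                          magnification = 100,
                          beamDiameterAtGratingMm = 8,
                          pixelSizeSampleNm = 46) {
  if (is.null(objectiveFocalLengthMm)) {
    stopifnot(is.numeric(magnification), magnification > 0)
    objectiveFocalLengthMm <- 200 / magnification
  }
  new("OpticalConfig",
      numericalAperture = as.numeric(numericalAperture),
      refractiveIndex = as.numeric(refractiveIndex),
      excitationWavelengthNm = as.numeric(excitationWavelengthNm),
      emissionWavelengthNm = as.numeric(emissionWavelengthNm),
      tubeFocalLengthMm = as.numeric(tubeFocalLengthMm),
      objectiveFocalLengthMm = as.numeric(objectiveFocalLengthMm),
      beamDiameterAtGratingMm = as.numeric(beamDiameterAtGratingMm),
      pixelSizeSampleNm = as.numeric(pixelSizeSampleNm))
}

#' Construct a TF axial sectioning model
#'
#' @param a sectioning parameter, 1/um^2 (`a = 0` is the wide-field limit)
#' @param z0 axial position of the temporal focus, um
#' @param amplitude peak signal above offset
#' @param offset additive baseline (0 for simulation)
#' @return a [TFSectioningModel-class]
#' @examples
#' m <- tfSectioningModel(a = 0.666)
#' fwhmFromSectioningParameter(m@a)  # ~2.45 um
#' @export
tfSectioningModel <- function(a = 0.666, z0 = 0, amplitude = 1, offset = 0) {
  new("TFSectioningModel", a = as.numeric(a), z0 = as.numeric(z0),
      amplitude = as.numeric(amplitude), offset = as.numeric(offset))
}

#' Axial two-photon response of temporal focusing
#'
#' Evaluates `offset + amplitude / (1 + a (z - z0)^2)`, the Lorentzian-form
#' two-photon signal from a plane at axial position `z`. The response is
#' maximal at the temporal focus `z0`, symmetric about it, and for
#' `a = 0` reduces to the constant wide-field limit.
#'
#' @param z axial positions, um (vectorized)
#' @param model a [TFSectioningModel-class]
#' @return the non-negative response at each `z`
#' @examples
#' m <- tfSectioningModel(a = 0.6664)
#' tfAxialProfile(0, m)       # 1 (peak)
#' tfAxialProfile(1.225, m)   # 0.5 (half maximum)
#' @export
tfAxialProfile <- function(z, model) {
  stopifnot(is(model, "TFSectioningModel"))
  validObject(model)
  model@offset + model@amplitude / (1 + model@a * (z - model@z0)^2)
}

#' FWHM of the TF axial response from its sectioning parameter
#'
#' The normalized response `1/(1 + a (z-z0)^2)` reaches half maximum
#' where `a (z-z0)^2 = 1`, so the full width is `2/sqrt(a)`. The inverse
#' relation is `a = 4 / FWHM^2`.
#'
#' @param a sectioning parameter, 1/um^2, must be > 0
#' @param fwhmUm axial FWHM, um, must be > 0
#' @return FWHM in um, or the sectioning parameter in 1/um^2
#' @examples
#' fwhmFromSectioningParameter(0.6664)  # 2.45 um
#' sectioningParameterFromFwhm(2.45)    # ~0.666
#' @export
fwhmFromSectioningParameter <- function(a) {
  if (!is.numeric(a) || any(a <= 0))
    stop("no finite FWHM: sectioning parameter 'a' must be > 0")
  2 / sqrt(a)
}

#' @rdname fwhmFromSectioningParameter
#' @export
sectioningParameterFromFwhm <- function(fwhmUm) {
  if (!is.numeric(fwhmUm) || any(fwhmUm <= 0))
    stop("fwhmUm must be > 0")
  4 / fwhmUm^2
}

#' Theoretical diffraction-limited lateral FWHM
#'
#' Wide-field FWHM approximation `0.51 * lambda_em / NA`. The returned
#' value carries a `"formula"` attribute documenting the convention.
#'
#' @param optics an [OpticalConfig-class]
#' @return lateral FWHM in nm, with attribute `formula`
#' @examples
#' lateralFwhmTheory(opticalConfig(emissionWavelengthNm = 705))  # ~256.8 nm
#' @export
lateralFwhmTheory <- function(optics) {
  stopifnot(is(optics, "OpticalConfig"))
  validObject(optics)
  out <- 0.51 * optics@emissionWavelengthNm / optics@numericalAperture
  attr(out, "formula") <- "0.51 * emission_wavelength / numerical_aperture"
  out
}

#' PSF width of an order-N temporal cumulant image
#'
#' For a Gaussian detection PSF, the order-N cumulant image has a PSF
#' narrower by a factor `sqrt(N)`.
#'
#' @param order cumulant order, integer >= 1 (1 = the mean image itself)
#' @param fwhm PSF FWHM of the mean image (any length unit)
#' @return `fwhm / sqrt(order)` in the same unit
#' @examples
#' sofiFwhm(2, 274)  # ~193.7
#' @export
sofiFwhm <- function(order, fwhm) {
  if (!is.numeric(order) || any(order < 1))
    stop("order must be an integer >= 1")
  stopifnot(is.numeric(fwhm), all(fwhm > 0))
  fwhm / sqrt(order)
}

#' Rescale a sectioning FWHM to a different emission wavelength
#'
#' Sectioning widths measured at one emission wavelength are carried to
#' another assuming linearity of sectioning in emission wavelength:
#' `fwhm * lambda_target / lambda_measured`.
#'
#' @param fwhm measured sectioning FWHM (any length unit)
#' @param lambdaMeasuredNm emission wavelength of the measurement, nm
#' @param lambdaTargetNm emission wavelength to rescale to, nm
#' @return rescaled FWHM in the unit of `fwhm`
#' @examples
#' scaleSectioningToWavelength(480, 605, 705)  # ~559.3
#' @export
scaleSectioningToWavelength <- function(fwhm, lambdaMeasuredNm,
                                        lambdaTargetNm) {
  stopifnot(is.numeric(fwhm), all(fwhm > 0),
            is.numeric(lambdaMeasuredNm), all(lambdaMeasuredNm > 0),
            is.numeric(lambdaTargetNm), all(lambdaTargetNm > 0))
  fwhm * lambdaTargetNm / lambdaMeasuredNm
}

#' Excitation-beam geometry at the sample
#'
#' The tube lens and objective form a 4f telescope that demagnifies the
#' excitation beam from the grating to the sample:
#' `demagnification = f_tube / f_objective`, and the illuminated field
#' diameter is the beam diameter at the grating divided by the
#' demagnification.
#'
#' @param optics an [OpticalConfig-class]
#' @return list with `demagnification` (dimensionless) and
#'   `fieldDiameterUm` (um)
#' @examples
#' excitationGeometry(opticalConfig())  # demag 200, field 40 um
#' @export
excitationGeometry <- function(optics) {
  stopifnot(is(optics, "OpticalConfig"))
  validObject(optics)
  demag <- optics@tubeFocalLengthMm / optics@objectiveFocalLengthMm
  fieldMm <- optics@beamDiameterAtGratingMm / demag
  list(demagnification = demag, fieldDiameterUm = fieldMm * 1000)
}

#' Construct a separable 3D Gaussian PSF
#'
#' @param lateralFwhmNm lateral FWHM, nm
#' @param axialFwhmNm axial FWHM, nm
#' @param normalization `"unit-integral"` (3D integral 1) or
#'   `"unit-peak"` (center value 1)
#' @return a [Psf3D-class]
#' @examples
#' psf <- gaussianPsf(274, 680)
#' psfValue(psf, 0, 0, 0)
#' @export
gaussianPsf <- function(lateralFwhmNm, axialFwhmNm,
                        normalization = c("unit-integral", "unit-peak")) {
  normalization <- match.arg(normalization)
  new("Psf3D", lateralFwhmNm = as.numeric(lateralFwhmNm),
      axialFwhmNm = as.numeric(axialFwhmNm), normalization = normalization)
}

#' Evaluate a separable Gaussian PSF
#'
#' With unit-peak normalization the center value is 1; with
#' unit-integral normalization the 3D integral equals 1 (value units
#' 1/nm^3). Arguments are recycled to a common length.
#'
#' @param psf a [Psf3D-class]
#' @param x,y lateral offsets from the center, nm
#' @param z axial offset from the center, nm
#' @return PSF value(s)
#' @export
psfValue <- function(psf, x, y, z) {
  stopifnot(is(psf, "Psf3D"))
  validObject(psf)
  sl <- sigmaFromFwhm(psf@lateralFwhmNm)
  sa <- sigmaFromFwhm(psf@axialFwhmNm)
  g <- exp(-(x^2 + y^2) / (2 * sl^2) - z^2 / (2 * sa^2))
  if (psf@normalization == "unit-integral")
    g <- g / ((2 * pi)^1.5 * sl^2 * sa)
  g
}
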