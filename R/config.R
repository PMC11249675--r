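#' @include AllClasses.R AllGenerics.R optics.R blinksim.R
NULL

.checkKeys <- function(x, allowed, section) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown key%s in '%s' config section: %s",
                 if (length(bad) > 1) "s" else "", section,
                 paste(bad, collapse = ", ")))
}

.zFromSpec <- function(zspec) {
  if (is.list(zspec) && !is.null(zspec$from)) {
    .checkKeys(zspec, c("from", "to", "by"), "plan$z_positions_um")
    seq(zspec$from, zspec$to, by = zspec$by)
  } else {
    as.numeric(unlist(zspec))
  }
}

#' Default run configuration
#'
#' The built-in study conditions: 1.4 NA oil objective, 1030 nm
#' excitation / 705 nm emission, detection PSF 274 nm lateral and 680 nm
#' axial FWHM, TF sectioning parameter 0.666 1/um^2 (2.45 um FWHM),
#' symmetric two-state blinking with ON fraction 0.5 and ~5-frame dwell,
#' a 200-count photon-number-resolving camera, and 300 frames x 1 ms per
#' z position on a 64 x 64 field of 46 nm pixels.
#'
#' @param seed master seed
#' @return a [RunConfig-class]
#' @export
defaultRunConfig <- function(seed = 1L) {
  new("RunConfig",
      optics = opticalConfig(),
      psf = gaussianPsf(274, 680),
      sectioning = tfSectioningModel(),
      excitationMode = "tf",
      kinetics = blinkKinetics(),
      camera = cameraModel(),
      plan = acquisitionPlan(seed = seed),
      sample = list(type = "flat_layer", n_emitters = 200,
                    field_um = 2.9, z_um = 0, brightness = 2500,
                    bleach_rate_per_frame = 0),
      analysis = list(order = 2L, lag = 0L, n_regions = 8L,
                      fit = "gaussian"),
      seed = as.integer(seed))
}

#' Read a run configuration from a YAML file
#'
#' Parses the structured configuration format. All lengths carry
#' explicit unit suffixes in the key names (`_nm`, `_mm`, `_um`, `_ms`).
#' Unknown keys in any section are errors (fail fast). Omitted sections
#' and keys fall back to [defaultRunConfig()] values.
#'
#' Sections: `optics` (numerical_aperture, refractive_index,
#' excitation_wavelength_nm, emission_wavelength_nm,
#' tube_focal_length_mm, magnification or objective_focal_length_mm,
#' beam_diameter_at_grating_mm, pixel_size_sample_nm), `psf`
#' (lateral_fwhm_nm, axial_fwhm_nm), `sectioning` (a_per_um2, z0_um),
#' `excitation` (mode: tf | widefield), `kinetics` (p_on_to_off,
#' p_off_to_on), `camera` (read_noise_sd_counts, offset_counts,
#' max_count, quantize, shot_noise), `plan` (n_frames, exposure_ms,
#' frame_rows, frame_cols, pixel_size_nm, z_positions_um — a list or a
#' `{from, to, by}` mapping), `sample` (type: flat_layer | grid |
#' explicit, plus its parameters), `analysis` (order, lag, n_regions,
#' fit), and a top-level `seed`.
#'
#' @param path YAML file path
#' @return a [RunConfig-class]
#' @seealso the annotated example under
#'   `system.file("extdata", "example_config.yaml", package = "sofisect")`
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  .checkKeys(raw, c("optics", "psf", "sectioning", "excitation",
                    "kinetics", "camera", "plan", "sample", "analysis",
                    "seed"), "top level")
  seed <- as.integer(raw$seed %||% 1L)
  base <- defaultRunConfig(seed)

  o <- raw$optics %||% list()
  .checkKeys(o, c("numerical_aperture", "refractive_index",
                  "excitation_wavelength_nm", "emission_wavelength_nm",
                  "tube_focal_length_mm", "objective_focal_length_mm",
                  "magnification", "beam_diameter_at_grating_mm",
                  "pixel_size_sample_nm"), "optics")
  optics <- opticalConfig(
    numericalAperture = o$numerical_aperture %||% 1.4,
    refractiveIndex = o$refractive_index %||% 1.515,
    excitationWavelengthNm = o$excitation_wavelength_nm %||% 1030,
    emissionWavelengthNm = o$emission_wavelength_nm %||% 705,
    tubeFocalLengthMm = o$tube_focal_length_mm %||% 400,
    objectiveFocalLengthMm = o$objective_focal_length_mm,
    magnification = o$magnification %||% 100,
    beamDiameterAtGratingMm = o$beam_diameter_at_grating_mm %||% 8,
    pixelSizeSampleNm = o$pixel_size_sample_nm %||% 46)

  p <- raw$psf %||% list()
  .checkKeys(p, c("lateral_fwhm_nm", "axial_fwhm_nm"), "psf")
  psf <- gaussianPsf(p$lateral_fwhm_nm %||% 274, p$axial_fwhm_nm %||% 680)

  s <- raw$sectioning %||% list()
  .checkKeys(s, c("a_per_um2", "z0_um"), "sectioning")
  sectioning <- tfSectioningModel(a = s$a_per_um2 %||% 0.666,
                                  z0 = s$z0_um %||% 0)

  e <- raw$excitation %||% list()
  .checkKeys(e, "mode", "excitation")
  mode <- e$mode %||% "tf"
  if (!mode %in% c("tf", "widefield"))
    stop("excitation mode must be 'tf' or 'widefield'")

  k <- raw$kinetics %||% list()
  .checkKeys(k, c("p_on_to_off", "p_off_to_on"), "kinetics")
  kinetics <- blinkKinetics(k$p_on_to_off %||% 0.2, k$p_off_to_on %||% 0.2)

  cm <- raw$camera %||% list()
  .checkKeys(cm, c("read_noise_sd_counts", "offset_counts", "max_count",
                   "quantize", "shot_noise"), "camera")
  camera <- cameraModel(readNoiseSd = cm$read_noise_sd_counts %||% 0.3,
                        offset = cm$offset_counts %||% 5,
                        maxCount = cm$max_count %||% 200,
                        quantize = cm$quantize %||% TRUE,
                        shotNoise = cm$shot_noise %||% TRUE)

  pl <- raw$plan %||% list()
  .checkKeys(pl, c("n_frames", "exposure_ms", "frame_rows", "frame_cols",
                   "pixel_size_nm", "z_positions_um"), "plan")
  plan <- acquisitionPlan(
    nFrames = pl$n_frames %||% 300,
    exposureMs = pl$exposure_ms %||% 1,
    frameShape = c(pl$frame_rows %||% 64, pl$frame_cols %||% 64),
    pixelSizeNm = pl$pixel_size_nm %||% 46,
    zPositionsUm = if (is.null(pl$z_positions_um)) 0 else
      .zFromSpec(pl$z_positions_um),
    seed = seed)

  sa <- raw$sample %||% base@sample
  .checkKeys(sa, c("type", "n_emitters", "field_um", "z_um", "brightness",
                   "margin_um", "jitter_frac", "x_um", "y_um",
                   "bleach_rate_per_frame"), "sample")
  sa$type <- sa$type %||% "flat_layer"
  if (!sa$type %in% c("flat_layer", "grid", "explicit"))
    stop("sample type must be 'flat_layer', 'grid' or 'explicit'")
  sa$bleach_rate_per_frame <- sa$bleach_rate_per_frame %||% 0

  an <- raw$analysis %||% list()
  .checkKeys(an, c("order", "lag", "n_regions", "fit"), "analysis")
  analysis <- list(order = as.integer(an$order %||% 2L),
                   lag = as.integer(an$lag %||% 0L),
                   n_regions = as.integer(an$n_regions %||% 8L),
                   fit = an$fit %||% "gaussian")
  if (!analysis$fit %in% c("gaussian", "eq1"))
    stop("analysis fit must be 'gaussian' or 'eq1'")

  new("RunConfig", optics = optics, psf = psf, sectioning = sectioning,
      excitationMode = mode, kinetics = kinetics, camera = camera,
      plan = plan, sample = sa, analysis = analysis, seed = seed)
}

#' Serialize a run configuration to YAML
#'
#' Writes the fully resolved configuration, suitable as a provenance
#' record: reading it back with [readRunConfig()] reproduces the run.
#'
#' @param config a [RunConfig-class]
#' @param path YAML file path
#' @return `path`, invisibly
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(is(config, "RunConfig"))
  o <- config@optics
  out <- list(
    seed = config@seed,
    optics = list(
      numerical_aperture = o@numericalAperture,
      refractive_index = o@refractiveIndex,
      excitation_wavelength_nm = o@excitationWavelengthNm,
      emission_wavelength_nm = o@emissionWavelengthNm,
      tube_focal_length_mm = o@tubeFocalLengthMm,
      objective_focal_length_mm = o@objectiveFocalLengthMm,
      beam_diameter_at_grating_mm = o@beamDiameterAtGratingMm,
      pixel_size_sample_nm = o@pixelSizeSampleNm),
    psf = list(lateral_fwhm_nm = config@psf@lateralFwhmNm,
               axial_fwhm_nm = config@psf@axialFwhmNm),
    sectioning = list(a_per_um2 = config@sectioning@a,
                      z0_um = config@sectioning@z0),
    excitation = list(mode = config@excitationMode),
    kinetics = list(p_on_to_off = config@kinetics@pOnToOff,
                    p_off_to_on = config@kinetics@pOffToOn),
    camera = list(read_noise_sd_counts = config@camera@readNoiseSd,
                  offset_counts = config@camera@offset,
                  max_count = config@camera@maxCount,
                  quantize = config@camera@quantize,
                  shot_noise = config@camera@shotNoise),
    plan = list(n_frames = config@plan@nFrames,
                exposure_ms = config@plan@exposureMs,
                frame_rows = config@plan@frameShape[1L],
                frame_cols = config@plan@frameShape[2L],
                pixel_size_nm = config@plan@pixelSizeNm,
                z_positions_um = as.list(config@plan@zPositionsUm)),
    sample = config@sample,
    analysis = config@analysis)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build the emitter sample described by a run configuration
#'
#' Sample types: `flat_layer` (uniform random positions in the field,
#' one plane; [flatLayerSample()]), `grid` (well-separated jittered grid;
#' [isolatedEmitterSample()]), `explicit` (positions given as `x_um`,
#' `y_um`, `z_um` lists).
#'
#' @param config a [RunConfig-class]
#' @return an [EmitterSet-class]
#' @export
buildSample <- function(config) {
  stopifnot(is(config, "RunConfig"))
  sa <- config@sample
  seed <- subSeed(config@seed, 999983L)  # sample placement stream
  switch(sa$type,
    flat_layer = flatLayerSample(
      nEmitters = sa$n_emitters %||% 200,
      fieldUm = sa$field_um %||%
        (config@plan@frameShape[2L] * config@plan@pixelSizeNm / 1000),
      zLayerUm = sa$z_um %||% 0,
      brightness = sa$brightness %||% 2500, seed = seed),
    grid = isolatedEmitterSample(
      nEmitters = sa$n_emitters %||% 20,
      fieldUm = sa$field_um %||%
        (config@plan@frameShape[2L] * config@plan@pixelSizeNm / 1000),
      brightness = sa$brightness %||% 2000,
      zUm = sa$z_um %||% 0,
      marginUm = sa$margin_um %||% 0.3,
      jitterFrac = sa$jitter_frac %||% 0.15, seed = seed),
    explicit = emitterSet(x = unlist(sa$x_um), y = unlist(sa$y_um),
                          z = unlist(sa$z_um %||% 0),
                          brightness = unlist(sa$brightness %||% 1000)),
    stop("unknown sample type: ", sa$type))
}
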