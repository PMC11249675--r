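#' @include AllClasses.R AllGenerics.R optics.R
NULL

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards. seed = NULL leaves the RNG stream untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic sub-seed from a master seed
#'
#' Counter-based derivation used to give each z position (or any indexed
#' sub-task) an independent, reproducible stream:
#' `((seed mod 1000003) * 2053 + index * 7919) mod (2^31 - 1)`.
#'
#' @param seed master seed (integer)
#' @param index non-negative counter (e.g. the z index)
#' @return a single integer seed below 2^31
#' @export
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed %% 1000003L) * 2053 +
              as.numeric(index) * 7919) %% 2147483647)
}

#' Construct blinking kinetics
#'
#' @param pOnToOff per-frame ON to OFF transition probability
#' @param pOffToOn per-frame OFF to ON transition probability
#' @return a [BlinkKinetics-class]
#' @examples
#' k <- blinkKinetics(0.2, 0.2)
#' onFraction(k)  # 0.5
#' @export
blinkKinetics <- function(pOnToOff = 0.2, pOffToOn = 0.2) {
  new("BlinkKinetics", pOnToOff = as.numeric(pOnToOff),
      pOffToOn = as.numeric(pOffToOn))
}

#' Construct a camera model
#'
#' @param readNoiseSd Gaussian read noise SD, counts
#' @param offset constant camera offset, counts
#' @param maxCount saturation clamp, counts (200-count photon-number
#'   resolving dynamic range by default)
#' @param quantize round to integer counts?
#' @param shotNoise apply Poisson shot noise?
#' @return a [CameraModel-class]
#' @export
cameraModel <- function(readNoiseSd = 0.3, offset = 5, maxCount = 200,
                        quantize = TRUE, shotNoise = TRUE) {
  new("CameraModel", readNoiseSd = as.numeric(readNoiseSd),
      offset = as.numeric(offset), maxCount = as.numeric(maxCount),
      quantize = isTRUE(quantize), shotNoise = isTRUE(shotNoise))
}

#' Construct an acquisition plan
#'
#' @param nFrames frames per z position (>= 2)
#' @param exposureMs exposure per frame, ms
#' @param frameShape integer (rows, cols)
#' @param pixelSizeNm pixel size at the sample, nm
#' @param zPositionsUm strictly increasing defocus values, um
#' @param seed master seed for the acquisition
#' @return an [AcquisitionPlan-class]
#' @examples
#' # a 21-plane volume at 300 nm spacing, 300 frames x 1 ms each
#' plan <- acquisitionPlan(zPositionsUm = seq(-3, 3, by = 0.3))
#' @export
acquisitionPlan <- function(nFrames = 300, exposureMs = 1,
                            frameShape = c(64, 64), pixelSizeNm = 46,
                            zPositionsUm = 0, seed = 1) {
  new("AcquisitionPlan", nFrames = as.integer(nFrames),
      exposureMs = as.numeric(exposureMs),
      frameShape = as.integer(frameShape),
      pixelSizeNm = as.numeric(pixelSizeNm),
      zPositionsUm = as.numeric(zPositionsUm), seed = as.integer(seed))
}

#' Construct an emitter set
#'
#' @param x,y lateral positions, um (origin at the field center)
#' @param z axial positions, um (recycled)
#' @param brightness expected detected photons per frame when ON (recycled)
#' @return an [EmitterSet-class]
#' @export
emitterSet <- function(x, y, z = 0, brightness = 1000) {
  n <- length(x)
  new("EmitterSet", x = as.numeric(x), y = as.numeric(y),
      z = rep_len(as.numeric(z), n),
      brightness = rep_len(as.numeric(brightness), n))
}

#' Construct a frame stack
#'
#' @param frames numeric array, dim (rows, cols, nFrames)
#' @param pixelSizeNm pixel size, nm
#' @param exposureMs exposure per frame, ms
#' @param metadata named list provenance record
#' @return a [FrameStack-class]
#' @export
frameStack <- function(frames, pixelSizeNm = 46, exposureMs = 1,
                       metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  new("FrameStack", frames = frames, pixelSizeNm = as.numeric(pixelSizeNm),
      exposureMs = as.numeric(exposureMs), metadata = metadata)
}

#' Construct a z-scan series
#'
#' @param zUm strictly increasing defocus values, um
#' @param stacks list of [FrameStack-class] objects, one per defocus
#' @return a [ZScanSeries-class]
#' @export
zScanSeries <- function(zUm, stacks) {
  new("ZScanSeries", zUm = as.numeric(zUm), stacks = stacks)
}

#' Simulate two-state Markov blinking traces
#'
#' Each emitter's ON/OFF state evolves as an independent two-state
#' Markov chain with the given per-frame transition probabilities,
#' started from its stationary distribution (ON probability
#' `pOffToOn / (pOnToOff + pOffToOn)`; 0.5 for the degenerate frozen
#' chain with both probabilities 0). Identical seeds reproduce identical
#' traces.
#'
#' @param kinetics a [BlinkKinetics-class]
#' @param nEmitters number of independent traces
#' @param nFrames trace length, >= 1
#' @param seed integer seed, or `NULL` to draw from the current RNG stream
#' @return integer 0/1 matrix, `nEmitters x nFrames`
#' @examples
#' tr <- simulateBlinkTraces(blinkKinetics(0.1, 0.3), 5, 100, seed = 1)
#' rowMeans(tr)  # around 0.75
#' @export
simulateBlinkTraces <- function(kinetics, nEmitters, nFrames, seed = NULL) {
  stopifnot(is(kinetics, "BlinkKinetics"), nEmitters >= 1, nFrames >= 1)
  validObject(kinetics)
  p10 <- kinetics@pOnToOff
  p01 <- kinetics@pOffToOn
  pOn <- onFraction(kinetics)
  if (is.na(pOn)) pOn <- 0.5
  .withSeed(seed, {
    s <- matrix(0L, nEmitters, nFrames)
    s[, 1L] <- as.integer(stats::runif(nEmitters) < pOn)
    if (nFrames > 1L) {
      U <- matrix(stats::runif(nEmitters * (nFrames - 1L)), nEmitters)
      for (t in 2:nFrames) {
        prev <- s[, t - 1L] == 1L
        u <- U[, t - 1L]
        s[, t] <- ifelse(prev, as.integer(u >= p10), as.integer(u < p01))
      }
    }
    s
  })
}

#' Excitation weight at an axial position
#'
#' Relative two-photon excitation of a plane at axial offset `z` from
#' the detection focus. In `"tf"` mode this is the axial response
#' [tfAxialProfile()] normalized to peak 1 (the Lorentzian-form response
#' already represents the two-photon, intensity-squared signal); in
#' `"widefield"` mode excitation is uniform: weight 1 everywhere.
#'
#' @param z axial offsets relative to the focus, um
#' @param mode `"tf"` or `"widefield"`
#' @param model a [TFSectioningModel-class] (required in `"tf"` mode)
#' @return weights in [0, 1]
#' @export
excitationWeight <- function(z, mode = c("tf", "widefield"), model = NULL) {
  mode <- match.arg(mode)
  if (mode == "widefield") return(rep(1, length(z)))
  stopifnot(is(model, "TFSectioningModel"))
  validObject(model)
  peak <- model@offset + model@amplitude
  if (peak <= 0) stop("TF model has zero peak response")
  tfAxialProfile(z, model) / peak
}

# Pixel-integrated lateral Gaussian footprint of each emitter:
# npix x nEmitters matrix (column-major pixel order, rows = y).
# Integrates to ~1 per emitter when the footprint lies inside the field;
# emitters near or beyond the edge contribute their truncated tail.
.lateralTemplates <- function(emitters, frameShape, pixelSizeNm, psf) {
  nr <- frameShape[1L]
  nc <- frameShape[2L]
  pix <- pixelSizeNm / 1000  # um
  sl <- sigmaFromFwhm(psf@lateralFwhmNm) / 1000  # um
  xEdges <- (0:nc) * pix - nc * pix / 2
  yEdges <- (0:nr) * pix - nr * pix / 2
  nE <- nEmitters(emitters)
  out <- matrix(0, nr * nc, nE)
  for (i in seq_len(nE)) {
    cx <- diff(stats::pnorm((xEdges - emitters@x[i]) / sl))
    cy <- diff(stats::pnorm((yEdges - emitters@y[i]) / sl))
    out[, i] <- as.vector(outer(cy, cx))
  }
  out
}

# Per-emitter expected ON photons/frame at a given defocus: brightness
# times excitation weight times axial detection envelope (unit peak).
.emitterCoef <- function(emitters, defocusUm, psf, excitationMode,
                         sectioning) {
  dz <- emitters@z - defocusUm
  sa <- sigmaFromFwhm(psf@axialFwhmNm) / 1000  # um
  wDet <- exp(-dz^2 / (2 * sa^2))
  wExc <- excitationWeight(dz, excitationMode, sectioning)
  emitters@brightness * wExc * wDet
}

# Expected photons -> camera counts (vector or matrix, shape preserved)
.applyCamera <- function(E, camera) {
  counts <- if (camera@shotNoise) {
    stats::rpois(length(E), as.vector(E))
  } else {
    as.vector(E)
  }
  counts <- counts + camera@offset
  if (camera@readNoiseSd > 0)
    counts <- counts + stats::rnorm(length(counts), sd = camera@readNoiseSd)
  if (camera@quantize) counts <- round(counts)
  counts <- pmin(pmax(counts, 0), camera@maxCount)
  if (is.matrix(E)) matrix(counts, nrow(E)) else counts
}

#' Render a single camera frame
#'
#' Forward imaging model for one frame: the noiseless expectation at
#' each pixel is the sum over ON emitters of brightness x excitation
#' weight x axial detection envelope x the lateral PSF integrated over
#' the pixel area; the camera model then applies Poisson shot noise to
#' the photon part, adds the offset and Gaussian read noise, optionally
#' quantizes, and clamps to the dynamic range. Emitters outside the
#' field silently contribute their truncated tail.
#'
#' @param emitters an [EmitterSet-class]
#' @param states integer 0/1 vector, one per emitter
#' @param defocusUm defocus of this frame, um
#' @param psf detection [Psf3D-class]
#' @param camera a [CameraModel-class]
#' @param excitationMode `"tf"` or `"widefield"`
#' @param sectioning [TFSectioningModel-class] (for `"tf"` mode)
#' @param frameShape integer (rows, cols)
#' @param pixelSizeNm pixel size, nm
#' @param seed integer seed for the noise draws, or `NULL`
#' @return numeric matrix of camera counts, dim `frameShape`
#' @export
renderFrame <- function(emitters, states, defocusUm, psf, camera,
                        excitationMode = c("widefield", "tf"),
                        sectioning = NULL, frameShape = c(64, 64),
                        pixelSizeNm = 46, seed = NULL) {
  excitationMode <- match.arg(excitationMode)
  stopifnot(is(emitters, "EmitterSet"), is(psf, "Psf3D"),
            is(camera, "CameraModel"),
            length(states) == nEmitters(emitters))
  frameShape <- as.integer(frameShape)
  Tm <- .lateralTemplates(emitters, frameShape, pixelSizeNm, psf)
  coef <- .emitterCoef(emitters, defocusUm, psf, excitationMode, sectioning)
  E <- Tm %*% (coef * as.numeric(states))
  counts <- .withSeed(seed, .applyCamera(E, camera))
  matrix(counts, frameShape[1L], frameShape[2L])
}

#' Simulate a blinking movie at one defocus
#'
#' Draws one blinking realization per emitter ([simulateBlinkTraces()]),
#' renders the expected photon image of every frame through the
#' separable Gaussian detection PSF and the chosen excitation mode, and
#' applies the camera model. All randomness derives from `seed`, so a
#' fixed seed reproduces a bit-identical stack.
#'
#' @param sample an [EmitterSet-class]
#' @param plan an [AcquisitionPlan-class] (frame count, geometry, seed)
#' @param psf detection [Psf3D-class]
#' @param kinetics a [BlinkKinetics-class]
#' @param camera a [CameraModel-class]
#' @param defocusUm defocus of this movie, um
#' @param excitationMode `"tf"` or `"widefield"`
#' @param sectioning [TFSectioningModel-class] (for `"tf"` mode)
#' @param bleachRatePerFrame exponential bleaching rate per frame
#'   (0 = photostable; used to emulate slow signal decay)
#' @param seed integer seed (defaults to the plan's seed)
#' @return a [FrameStack-class]
#' @examples
#' em <- emitterSet(0, 0, brightness = 500)
#' plan <- acquisitionPlan(nFrames = 50, frameShape = c(32, 32), seed = 7)
#' st <- simulateMovie(em, plan, gaussianPsf(274, 680),
#'                     blinkKinetics(), cameraModel())
#' @export
simulateMovie <- function(sample, plan, psf, kinetics, camera,
                          defocusUm = 0,
                          excitationMode = c("widefield", "tf"),
                          sectioning = NULL, bleachRatePerFrame = 0,
                          seed = plan@seed) {
  excitationMode <- match.arg(excitationMode)
  stopifnot(is(sample, "EmitterSet"), is(plan, "AcquisitionPlan"),
            is(psf, "Psf3D"), is(kinetics, "BlinkKinetics"),
            is(camera, "CameraModel"))
  validObject(plan)
  nF <- plan@nFrames
  if (nF < 2L) stop("nFrames must be >= 2")
  counts <- .withSeed(seed, {
    traces <- simulateBlinkTraces(kinetics, nEmitters(sample), nF)
    coef <- .emitterCoef(sample, defocusUm, psf, excitationMode, sectioning)
    S <- coef * traces  # nEmitters x nFrames expected ON photons
    if (bleachRatePerFrame > 0) S <- applyBleaching(S, bleachRatePerFrame)
    Tm <- .lateralTemplates(sample, plan@frameShape, plan@pixelSizeNm, psf)
    .applyCamera(Tm %*% S, camera)
  })
  new("FrameStack",
      frames = array(counts, dim = c(plan@frameShape, nF)),
      pixelSizeNm = plan@pixelSizeNm, exposureMs = plan@exposureMs,
      metadata = list(
        defocusUm = defocusUm, seed = seed,
        excitationMode = excitationMode,
        bleachRatePerFrame = bleachRatePerFrame,
        psfLateralFwhmNm = psf@lateralFwhmNm,
        psfAxialFwhmNm = psf@axialFwhmNm,
        nEmitters = nEmitters(sample),
        camera = list(readNoiseSd = camera@readNoiseSd,
                      offset = camera@offset, maxCount = camera@maxCount,
                      quantize = camera@quantize,
                      shotNoise = camera@shotNoise),
        kinetics = list(pOnToOff = kinetics@pOnToOff,
                        pOffToOn = kinetics@pOffToOn)))
}

#' Simulate a z-scan series of movies
#'
#' One movie per defocus in `plan@zPositionsUm`. Blinking and noise are
#' re-drawn independently per z position using the documented sub-seed
#' scheme ([subSeed()] of the plan seed and the z index), matching
#' separately recorded movies.
#'
#' @inheritParams simulateMovie
#' @return a [ZScanSeries-class]
#' @export
simulateZScan <- function(sample, plan, psf, kinetics, camera,
                          excitationMode = c("widefield", "tf"),
                          sectioning = NULL, bleachRatePerFrame = 0) {
  excitationMode <- match.arg(excitationMode)
  zs <- plan@zPositionsUm
  stacks <- lapply(seq_along(zs), function(k) {
    simulateMovie(sample, plan, psf, kinetics, camera,
                  defocusUm = zs[k], excitationMode = excitationMode,
                  sectioning = sectioning,
                  bleachRatePerFrame = bleachRatePerFrame,
                  seed = subSeed(plan@seed, k))
  })
  zScanSeries(zs, stacks)
}

#' Uniform flat-layer sample
#'
#' Emitters placed uniformly at random in a rectangular lateral field,
#' all in one axial plane — emulating a spin-coated quantum-dot layer
#' used to measure axial sectioning.
#'
#' @param nEmitters number of emitters, >= 1
#' @param fieldUm lateral field extent, um (scalar, or (width, height))
#' @param zLayerUm axial position of the layer, um
#' @param brightness expected detected photons/frame when ON
#' @param seed integer seed, or `NULL`
#' @return an [EmitterSet-class]
#' @export
flatLayerSample <- function(nEmitters, fieldUm, zLayerUm = 0,
                            brightness = 2500, seed = NULL) {
  stopifnot(nEmitters >= 1, all(fieldUm > 0))
  fieldUm <- rep_len(as.numeric(fieldUm), 2L)
  .withSeed(seed, {
    emitterSet(x = stats::runif(nEmitters, -fieldUm[1] / 2, fieldUm[1] / 2),
               y = stats::runif(nEmitters, -fieldUm[2] / 2, fieldUm[2] / 2),
               z = zLayerUm, brightness = brightness)
  })
}

#' Well-separated emitters on a jittered grid
#'
#' Places emitters on a square grid with random sub-cell jitter,
#' guaranteeing a minimum pairwise separation of
#' `(1 - 2 jitterFrac) x cell` — isolated spots suitable for
#' emitter-wise PSF measurements.
#'
#' @param nEmitters number of emitters
#' @param fieldUm lateral field extent, um (square)
#' @param brightness expected detected photons/frame when ON
#' @param zUm axial position, um
#' @param marginUm border kept free of emitters, um
#' @param jitterFrac jitter amplitude as a fraction of the cell, < 0.5
#' @param seed integer seed, or `NULL`
#' @return an [EmitterSet-class]
#' @export
isolatedEmitterSample <- function(nEmitters, fieldUm, brightness = 2000,
                                  zUm = 0, marginUm = 0.3,
                                  jitterFrac = 0.15, seed = NULL) {
  stopifnot(nEmitters >= 1, fieldUm > 2 * marginUm, jitterFrac < 0.5)
  g <- ceiling(sqrt(nEmitters))
  usable <- fieldUm - 2 * marginUm
  cell <- usable / g
  centers <- -usable / 2 + (seq_len(g) - 0.5) * cell
  idx <- seq_len(nEmitters)
  cx <- centers[((idx - 1L) %% g) + 1L]
  cy <- centers[((idx - 1L) %/% g) + 1L]
  .withSeed(seed, {
    emitterSet(
      x = cx + stats::runif(nEmitters, -jitterFrac, jitterFrac) * cell,
      y = cy + stats::runif(nEmitters, -jitterFrac, jitterFrac) * cell,
      z = zUm, brightness = brightness)
  })
}

#' Apply exponential bleaching to a brightness series
#'
#' Multiplies the expectation of frame `t` (0-based) by
#' `exp(-decayRatePerFrame * t)`. Accepts a single trace (numeric
#' vector over frames) or a matrix with frames along columns.
#'
#' @param x numeric vector (frames) or matrix (emitters x frames)
#' @param decayRatePerFrame exponential decay rate per frame, >= 0
#' @return `x` with bleaching applied
#' @examples
#' applyBleaching(c(1, 1, 1), log(2))  # 1, 0.5, 0.25
#' @export
applyBleaching <- function(x, decayRatePerFrame) {
  stopifnot(is.numeric(decayRatePerFrame), decayRatePerFrame >= 0)
  if (decayRatePerFrame == 0) return(x)
  if (is.matrix(x)) {
    f <- exp(-decayRatePerFrame * (seq_len(ncol(x)) - 1))
    x * rep(f, each = nrow(x))
  } else {
    x * exp(-decayRatePerFrame * (seq_along(x) - 1))
  }
}
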