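# shared builders for the test suite

defaultPsf <- function() gaussianPsf(274, 680)

noiselessCamera <- function(offset = 0) {
  cameraModel(readNoiseSd = 0, offset = offset, maxCount = 1e9,
              quantize = FALSE, shotNoise = FALSE)
}

# a 1-pixel stack holding one intensity trace
traceStack <- function(trace) {
  frameStack(array(trace, dim = c(1, 1, length(trace))))
}

# direct loop-based central-moment oracle, independent of the package's
# vectorized estimators
oracleCumulant2 <- function(x, lag = 0) {
  n <- length(x)
  d <- x - mean(x)
  if (lag == 0) {
    s <- 0
    for (t in 1:n) s <- s + d[t]^2
    s / (n - 1)
  } else {
    s <- 0
    for (t in 1:(n - lag)) s <- s + d[t] * d[t + lag]
    s / (n - lag - 1)
  }
}

oracleCumulant3 <- function(x) {
  n <- length(x)
  d <- x - mean(x)
  s <- 0
  for (t in 1:n) s <- s + d[t]^3
  n * s / ((n - 1) * (n - 2))
}

# noiseless eq-1 sectioning curve
eq1Curve <- function(a = 0.6664, z0 = 0, amplitude = 1, offset = 0,
                     z = seq(-6, 6, 0.25), unc = 0) {
  m <- tfSectioningModel(a = a, z0 = z0, amplitude = amplitude,
                         offset = offset)
  new("SectioningCurve", zUm = z, signal = tfAxialProfile(z, m),
      uncertainty = rep(unc, length(z)), nRegions = 1L)
}

# point-sampled 2D Gaussian spot image (pixel centers), FWHM in nm
gaussianSpotImage <- function(n = 41, fwhmNm = 274, pixNm = 46,
                              amplitude = 1000, offset = 10,
                              centerPx = (n + 1) / 2) {
  s <- sigmaFromFwhm(fwhmNm)
  r <- (seq_len(n) - centerPx) * pixNm
  outer(r, r, function(y, x) offset + amplitude * exp(-(x^2 + y^2) / (2 * s^2)))
}
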