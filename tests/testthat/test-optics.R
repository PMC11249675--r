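test_that("TF axial profile peaks at the temporal focus and matches direct evaluation", {
  m <- tfSectioningModel(a = 0.6664, z0 = 0, amplitude = 1, offset = 0)
  expect_equal(tfAxialProfile(0, m), 1)
  # half maximum where a (z - z0)^2 = 1
  expect_equal(tfAxialProfile(1.225, m), 1 / (1 + 0.6664 * 1.225^2))
  expect_equal(tfAxialProfile(1.225, m), 0.5, tolerance = 1e-4)
  # wide-field limit: constant amplitude + offset
  m0 <- tfSectioningModel(a = 0, amplitude = 2, offset = 0.5)
  expect_equal(tfAxialProfile(c(-10, 0, 3), m0), rep(2.5, 3))
  # shifted focus
  m2 <- tfSectioningModel(a = 1, z0 = 1.5)
  expect_equal(tfAxialProfile(1.5, m2), 1)
})

test_that("TF axial profile is even about z0 and strictly decreasing in |z - z0|", {
  m <- tfSectioningModel(a = 0.9, z0 = 0.4)
  dz <- seq(0.05, 5, by = 0.05)
  expect_equal(tfAxialProfile(m@z0 + dz, m), tfAxialProfile(m@z0 - dz, m))
  expect_true(all(diff(tfAxialProfile(m@z0 + dz, m)) < 0))
})

test_that("sectioning parameter and FWHM round-trip; examples agree", {
  expect_equal(fwhmFromSectioningParameter(4), 1)
  expect_equal(fwhmFromSectioningParameter(1), 2)
  expect_equal(fwhmFromSectioningParameter(0.6664), 2 / sqrt(0.6664))
  expect_equal(fwhmFromSectioningParameter(0.6664), 2.45, tolerance = 2e-3)
  a <- c(0.1, 0.666, 4, 123)
  expect_equal(sectioningParameterFromFwhm(fwhmFromSectioningParameter(a)), a)
  expect_error(fwhmFromSectioningParameter(0), "no finite FWHM")
  expect_error(fwhmFromSectioningParameter(-1), "no finite FWHM")
})

test_that("theoretical lateral FWHM follows 0.51 lambda / NA", {
  cfg <- opticalConfig(emissionWavelengthNm = 705, numericalAperture = 1.4)
  v <- lateralFwhmTheory(cfg)
  expect_equal(as.numeric(v), 0.51 * 705 / 1.4)
  expect_equal(as.numeric(v), 255, tolerance = 0.015)  # reference value, ~1% rounding
  expect_equal(
    as.numeric(lateralFwhmTheory(opticalConfig(emissionWavelengthNm = 605))),
    220.4, tolerance = 1e-3)
  # linearity in wavelength
  v2 <- lateralFwhmTheory(opticalConfig(emissionWavelengthNm = 1410))
  expect_equal(as.numeric(v2), 2 * as.numeric(v))
  expect_match(attr(v, "formula"), "0.51")
})

test_that("cumulant-order PSF scaling is fwhm / sqrt(order)", {
  expect_equal(sofiFwhm(1, 274), 274)
  expect_equal(sofiFwhm(2, 274), 274 / sqrt(2))
  expect_equal(sofiFwhm(2, 274), 193.7, tolerance = 1e-3)
  expect_equal(sofiFwhm(4, 400), 200)
  f <- c(0.3, 100, 7e4)
  expect_equal(sofiFwhm(2, f) / f, rep(1 / sqrt(2), 3))
  expect_error(sofiFwhm(0, 100), "order")
})

test_that("sectioning rescales linearly with emission wavelength", {
  expect_equal(scaleSectioningToWavelength(480, 605, 705), 480 * 705 / 605)
  expect_equal(scaleSectioningToWavelength(480, 605, 705), 559.3,
               tolerance = 1e-4)
  expect_equal(scaleSectioningToWavelength(123, 700, 700), 123)
  expect_equal(scaleSectioningToWavelength(100, 500, 1000), 200)
})

test_that("excitation geometry reproduces the 4f demagnification", {
  g <- excitationGeometry(opticalConfig())  # f_TL 400, 100x -> 2 mm, 8 mm beam
  expect_identical(g$demagnification, 200)
  expect_identical(g$fieldDiameterUm, 40)
  gEq <- excitationGeometry(opticalConfig(tubeFocalLengthMm = 2,
                                          objectiveFocalLengthMm = 2,
                                          beamDiameterAtGratingMm = 8))
  expect_equal(gEq$demagnification, 1)
  expect_equal(gEq$fieldDiameterUm, 8000)  # beam diameter, in um
  g2 <- excitationGeometry(opticalConfig(tubeFocalLengthMm = 200))
  expect_equal(g2$demagnification, 100)
  expect_equal(g2$fieldDiameterUm, 80)
})

test_that("objective focal length derives from magnification when not given", {
  expect_equal(opticalConfig(magnification = 60)@objectiveFocalLengthMm,
               200 / 60)
  expect_equal(opticalConfig(objectiveFocalLengthMm = 3,
                             magnification = 60)@objectiveFocalLengthMm, 3)
})

test_that("Gaussian PSF normalizations hold", {
  pk <- gaussianPsf(274, 680, "unit-peak")
  expect_equal(psfValue(pk, 0, 0, 0), 1)
  # half maximum at a lateral offset of FWHM/2
  expect_equal(psfValue(pk, 137, 0, 0), 0.5)
  expect_equal(psfValue(pk, 0, 0, 340), 0.5)
  # squared evaluator has FWHM shrunk by sqrt(2)
  expect_equal(psfValue(pk, 274 / (2 * sqrt(2)), 0, 0)^2, 0.5)
  # unit-integral: numeric 3D integral over +/-5 sigma equals 1 to 1e-4
  ui <- gaussianPsf(200, 500, "unit-integral")
  sl <- sigmaFromFwhm(200)
  sa <- sigmaFromFwhm(500)
  gl <- seq(-5 * sl, 5 * sl, length.out = 81)
  ga <- seq(-5 * sa, 5 * sa, length.out = 81)
  dl <- diff(gl)[1]
  da <- diff(ga)[1]
  marg1d <- function(g, s) sum(exp(-g^2 / (2 * s^2))) * diff(g)[1] /
    sqrt(2 * pi * s^2)
  tot <- marg1d(gl, sl)^2 * marg1d(ga, sa)
  expect_equal(tot, 1, tolerance = 1e-4)
  # and pointwise the unit-integral value is the normalized unit-peak one
  expect_equal(psfValue(ui, 50, -30, 120),
               psfValue(gaussianPsf(200, 500, "unit-peak"), 50, -30, 120) /
                 ((2 * pi)^1.5 * sl^2 * sa))
})

test_that("invalid optical parameters are rejected", {
  expect_error(opticalConfig(numericalAperture = 1.7, refractiveIndex = 1.33),
               "cannot exceed")
  expect_error(opticalConfig(emissionWavelengthNm = -5), "positive")
  expect_error(tfSectioningModel(a = -1), "a must be")
  expect_error(gaussianPsf(-274, 680), "positive")
})
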