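test_that("region-summed curves average tiles with their spread", {
  # uniform image: mean = v * pixels per region, zero spread
  imgs <- lapply(c(2, 5), function(v) matrix(v, 4, 8))
  cur <- summedSignalCurve(imgs, c(0, 1), nRegions = 8)
  expect_equal(cur@signal, c(2, 5) * 4)  # 32 px / 8 regions = 4 px each
  expect_equal(cur@uncertainty, c(0, 0))
  # single z gives a one-point curve
  one <- summedSignalCurve(list(matrix(1, 2, 4)), 0.3, nRegions = 8)
  expect_length(one@zUm, 1)
  expect_error(summedSignalCurve(list(matrix(1, 3, 3), matrix(1, 4, 4)),
                                 c(0, 1)), "share one shape")
  expect_error(summedSignalCurve(list(matrix(1, 3, 5)), 0, nRegions = 8),
               "does not tile")
})

test_that("tile sums equal a brute-force loop over regions", {
  set.seed(80)
  img <- matrix(rnorm(12 * 8), 12, 8)
  cur <- summedSignalCurve(list(img), 0, nRegions = 8)  # 2 x 4 grid
  tiles <- numeric(0)
  for (tc in 0:3) for (tr in 0:1) {
    tiles <- c(tiles, sum(img[tr * 6 + 1:6, tc * 2 + 1:2]))
  }
  expect_equal(cur@signal, mean(tiles))
  expect_equal(cur@uncertainty, sd(tiles))
})

test_that("noiseless model curves are recovered to 1e-6", {
  # Lorentzian-form axial response
  f <- fitTfSectioning(eq1Curve(a = 0.6664, z0 = 0.3, amplitude = 2.5,
                                offset = 0.2))
  expect_true(f@converged)
  expect_equal(f@parameters[["a"]], 0.6664, tolerance = 1e-6)
  expect_equal(f@parameters[["z0"]], 0.3, tolerance = 1e-6)
  expect_equal(f@parameters[["A"]], 2.5, tolerance = 1e-6)
  expect_equal(fwhm(f), 2 / sqrt(0.6664), tolerance = 1e-6)
  expect_equal(fwhm(f), 2.45, tolerance = 2e-3)
  expect_lt(f@residualNorm, 1e-8)
  # Gaussian with sigma 0.204 um -> FWHM 0.480 um
  z <- seq(-1.5, 1.5, 0.05)
  g <- new("SectioningCurve", zUm = z,
           signal = 3 * exp(-z^2 / (2 * 0.204^2)) + 0.5,
           uncertainty = rep(0, length(z)), nRegions = 1L)
  fg <- fitGaussianSectioning(g)
  expect_true(fg@converged)
  expect_equal(fwhm(fg), 2 * sqrt(2 * log(2)) * 0.204, tolerance = 1e-6)
  expect_equal(fwhm(fg), 0.480, tolerance = 1e-3)
  expect_equal(fg@parameters[["z0"]], 0, tolerance = 1e-8)
  expect_lt(fg@residualNorm, 1e-8)
})

test_that("adding a constant to the signal only shifts the fitted offset", {
  base <- eq1Curve(a = 1.2, amplitude = 1, offset = 0)
  up <- base
  up@signal <- base@signal + 7
  f0 <- fitTfSectioning(base)
  f7 <- fitTfSectioning(up)
  expect_equal(f7@parameters[["o"]], f0@parameters[["o"]] + 7,
               tolerance = 1e-6)
  for (p in c("A", "z0", "a"))
    expect_equal(f7@parameters[[p]], f0@parameters[[p]], tolerance = 1e-6)
})

test_that("under 5% multiplicative noise the recovered FWHM is accurate", {
  # region-averaged Monte Carlo: 8 regions, weighted fit, many seeds
  rec <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    z <- seq(-6, 6, 0.25)
    f0 <- tfAxialProfile(z, tfSectioningModel(a = 0.666))
    regions <- replicate(8, f0 * (1 + 0.05 * rnorm(length(z))))
    cur <- new("SectioningCurve", zUm = z, signal = rowMeans(regions),
               uncertainty = apply(regions, 1, sd), nRegions = 8L)
    fwhm(fitTfSectioning(cur))
  }, numeric(1))
  truth <- 2 / sqrt(0.666)
  expect_true(all(abs(rec - truth) < 0.3))  # reference-scale error bound
  expect_lt(abs(mean(rec) - truth) / truth, 0.02)  # < 2% bias
})

test_that("a non-identifiable curve reports failure instead of nonsense", {
  flat <- new("SectioningCurve", zUm = seq(-2, 2, 0.5),
              signal = rep(1, 9), uncertainty = rep(0, 9), nRegions = 1L)
  f <- fitTfSectioning(flat)
  expect_false(f@converged)
  expect_true(is.na(fwhm(f)))
  expect_match(f@status, ".")
})

test_that("PSF extraction recovers a synthetic spot within 1%", {
  img <- gaussianSpotImage(41, fwhmNm = 274)
  ps <- estimatePsfFwhm(img, 46)
  expect_equal(nEmitters(ps), 1L)
  expect_equal(meanFwhm(ps), 274, tolerance = 0.01)
  # global intensity scaling leaves the estimate unchanged
  ps10 <- estimatePsfFwhm(img * 10, 46)
  expect_equal(ps10@fwhmNm, ps@fwhmNm)
  # integer-pixel translation away from the border leaves it unchanged
  sh <- gaussianSpotImage(41, fwhmNm = 274, centerPx = 15)
  expect_equal(meanFwhm(estimatePsfFwhm(sh, 46)), meanFwhm(ps),
               tolerance = 1e-6)
})

test_that("PSF extraction separates and measures several emitters", {
  s <- sigmaFromFwhm(274)
  n <- 64
  r <- (seq_len(n) - 0.5) * 46
  centers <- list(c(700, 700), c(700, 2200), c(2200, 1400))
  img <- matrix(5, n, n)
  for (ce in centers) {
    img <- img + 800 * outer(r - ce[1], r - ce[2],
                             function(y, x) exp(-(x^2 + y^2) / (2 * s^2)))
  }
  ps <- estimatePsfFwhm(img, 46)
  expect_equal(nEmitters(ps), 3L)
  expect_equal(mean(ps@fwhmNm), 274, tolerance = 0.02)
  # a flat image yields an explicit empty result
  empty <- estimatePsfFwhm(matrix(1, 32, 32), 46)
  expect_equal(nEmitters(empty), 0L)
  expect_match(empty@status, "threshold|maximum")
})

test_that("resolution improvement propagates the two spreads", {
  a <- psfStats(rep(100, 3))
  expect_equal(resolutionImprovement(a, a)[["ratio"]], 1)
  # reference-style values 274 +/- 18 vs 199 +/- 12 -> 1.38 consistent with sqrt(2)
  set.seed(90)
  wide <- psfStats(rnorm(200, 274, 18))
  sofi <- psfStats(rnorm(200, 199, 12))
  ri <- resolutionImprovement(wide, sofi)
  expect_equal(ri[["ratio"]], 274 / 199, tolerance = 0.02)
  expect_lt(abs(ri[["ratio"]] - sqrt(2)), 2 * ri[["uncertainty"]])
  # invariant under common rescaling
  wide2 <- psfStats(wide@fwhmNm * 3.7)
  sofi2 <- psfStats(sofi@fwhmNm * 3.7)
  ri2 <- resolutionImprovement(wide2, sofi2)
  expect_equal(ri2[["ratio"]], ri[["ratio"]])
  expect_equal(ri2[["uncertainty"]], ri[["uncertainty"]])
})
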