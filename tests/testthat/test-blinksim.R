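test_that("blink traces reproduce the stationary ON fraction of the chain", {
  # symmetric chain with p = 0.5 transitions is an iid fair coin
  tr <- simulateBlinkTraces(blinkKinetics(0.5, 0.5), 1, 10000, seed = 101)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(mean(tr) - 0.5), 3 * se)
  # asymmetric chain: stationary ON fraction 0.1 / 0.4 = 0.25; the mean of
  # a correlated chain has variance p q (1 + rho) / (1 - rho) / n,
  # rho = 1 - p01 - p10 = 0.6
  tr2 <- simulateBlinkTraces(blinkKinetics(pOnToOff = 0.3, pOffToOn = 0.1),
                             1, 10000, seed = 102)
  se2 <- sqrt(0.25 * 0.75 * (1.6 / 0.4) / 10000)
  expect_lt(abs(mean(tr2) - 0.25), 3 * se2)
})

test_that("an absorbing ON state yields an all-ON trace", {
  tr <- simulateBlinkTraces(blinkKinetics(pOnToOff = 0, pOffToOn = 0.4),
                            3, 200, seed = 5)
  expect_true(all(tr == 1L))  # stationary start is ON, and ON is absorbing
})

test_that("traces are reproducible and mutually independent-ish", {
  k <- blinkKinetics(0.2, 0.2)
  a <- simulateBlinkTraces(k, 10, 500, seed = 42)
  b <- simulateBlinkTraces(k, 10, 500, seed = 42)
  expect_identical(a, b)
  c2 <- simulateBlinkTraces(k, 10, 500, seed = 43)
  expect_false(identical(a, c2))
})

test_that("excitation weight is 1 for widefield and follows the TF profile", {
  expect_equal(excitationWeight(c(-3, 0, 7), "widefield"), rep(1, 3))
  m <- tfSectioningModel(a = 0.6664)
  expect_equal(excitationWeight(0, "tf", m), 1)
  expect_equal(excitationWeight(1.225, "tf", m), 0.5, tolerance = 1e-4)
  expect_equal(excitationWeight(-1.225, "tf", m),
               excitationWeight(1.225, "tf", m))
})

test_that("rendered frames obey the forward model and photon conservation", {
  psf <- defaultPsf()
  # no emitters, no noise -> uniform camera offset
  none <- emitterSet(numeric(0), numeric(0))
  fr <- renderFrame(none, integer(0), 0, psf, noiselessCamera(offset = 7),
                    frameShape = c(16, 16))
  expect_equal(fr, matrix(7, 16, 16))
  # one ON emitter at focus: image sum = brightness + offset * npix
  one <- emitterSet(0, 0, 0, brightness = 1000)
  fr2 <- renderFrame(one, 1L, 0, psf, noiselessCamera(offset = 2),
                     frameShape = c(64, 64))
  expect_equal(sum(fr2), 1000 + 2 * 64^2, tolerance = 1e-3)
  # same emitter OFF -> offset everywhere
  fr3 <- renderFrame(one, 0L, 0, psf, noiselessCamera(offset = 2),
                     frameShape = c(64, 64))
  expect_equal(fr3, matrix(2, 64, 64))
  # defocus attenuates by the axial envelope; off-center position shifts
  fr4 <- renderFrame(one, 1L, 0.34, psf, noiselessCamera(),
                     frameShape = c(64, 64))
  expect_equal(sum(fr4), 1000 * exp(-0.34^2 / (2 * (sigmaFromFwhm(680) / 1000)^2)),
               tolerance = 1e-3)
})

test_that("movies are deterministic under a fixed seed and respect the clamp", {
  em <- flatLayerSample(10, 1.5, brightness = 4000, seed = 9)
  plan <- acquisitionPlan(nFrames = 40, frameShape = c(32, 32), seed = 11)
  cam <- cameraModel(maxCount = 120)
  a <- simulateMovie(em, plan, defaultPsf(), blinkKinetics(), cam)
  b <- simulateMovie(em, plan, defaultPsf(), blinkKinetics(), cam)
  expect_identical(frames(a), frames(b))
  expect_true(all(frames(a) >= 0 & frames(a) <= 120))
  expect_true(all(frames(a) == round(frames(a))))  # quantized counts
  # a different seed changes the realization
  c2 <- simulateMovie(em, plan, defaultPsf(), blinkKinetics(), cam, seed = 12)
  expect_false(identical(frames(a), frames(c2)))
})

test_that("an always-ON emitter without noise gives identical frames", {
  em <- emitterSet(0.2, -0.1, 0, brightness = 800)
  plan <- acquisitionPlan(nFrames = 5, frameShape = c(24, 24), seed = 3)
  st <- simulateMovie(em, plan, defaultPsf(),
                      blinkKinetics(pOnToOff = 0, pOffToOn = 1),
                      noiselessCamera())
  f <- frames(st)
  for (t in 2:5) expect_equal(f[, , t], f[, , 1])
})

test_that("stack mean of a duty-0.5 emitter is half the always-ON image", {
  em <- emitterSet(0, 0, 0, brightness = 1000)
  plan <- acquisitionPlan(nFrames = 300, frameShape = c(32, 32), seed = 21)
  on <- simulateMovie(em, plan, defaultPsf(),
                      blinkKinetics(pOnToOff = 0, pOffToOn = 1),
                      noiselessCamera())
  half <- simulateMovie(em, plan, defaultPsf(),
                        blinkKinetics(0.5, 0.5), noiselessCamera())
  onFrac <- mean(rowMeans(matrix(frames(half), 32 * 32)) > 0) # not used; sanity
  expect_equal(sum(meanImage(half)), 0.5 * sum(meanImage(on)),
               tolerance = 3 * sqrt(0.25 / 300) / 0.5)
})

test_that("z-scans draw independent blinking per plane and match single movies", {
  em <- flatLayerSample(5, 1, brightness = 500, seed = 2)
  plan <- acquisitionPlan(nFrames = 20, frameShape = c(16, 16),
                          zPositionsUm = c(-0.5, 0, 0.5), seed = 33)
  ser <- simulateZScan(em, plan, defaultPsf(), blinkKinetics(), cameraModel())
  expect_s4_class(ser, "ZScanSeries")
  expect_equal(length(ser), 3L)
  expect_equal(zPositions(ser), c(-0.5, 0, 0.5))
  # entry k equals a direct movie with the documented sub-seed
  direct <- simulateMovie(em, plan, defaultPsf(), blinkKinetics(),
                          cameraModel(), defocusUm = 0.5,
                          seed = subSeed(33L, 3))
  expect_identical(frames(ser[[3]]), frames(direct))
  # different planes have different realizations
  expect_false(identical(frames(ser[[1]]), frames(ser[[2]])))
  # single z reduces to simulate_movie
  plan1 <- acquisitionPlan(nFrames = 20, frameShape = c(16, 16),
                           zPositionsUm = 0, seed = 33)
  ser1 <- simulateZScan(em, plan1, defaultPsf(), blinkKinetics(), cameraModel())
  expect_equal(length(ser1), 1L)
})

test_that("widefield flat-layer z-scan is flat in summed mean signal", {
  em <- flatLayerSample(30, 1.8, brightness = 1500, seed = 7)
  plan <- acquisitionPlan(nFrames = 30, frameShape = c(48, 48),
                          zPositionsUm = seq(-0.4, 0.4, 0.2), seed = 8)
  # axial envelope removed: very large axial FWHM
  ser <- simulateZScan(em, plan, gaussianPsf(274, 1e6),
                       blinkKinetics(pOnToOff = 0, pOffToOn = 1),
                       noiselessCamera())
  sums <- vapply(seq_len(length(ser)),
                 function(i) sum(meanImage(ser[[i]])), numeric(1))
  expect_lt(diff(range(sums)) / mean(sums), 1e-6)
})

test_that("flat-layer samples are uniform in the requested field", {
  em <- flatLayerSample(400, c(3, 2), zLayerUm = 0.7, brightness = 100,
                        seed = 13)
  expect_true(all(em@z == 0.7))
  expect_true(all(abs(em@x) <= 1.5) && all(abs(em@y) <= 1))
  # mean nearest-neighbour distance of a uniform pattern ~ 1/(2 sqrt(density))
  d <- as.matrix(dist(cbind(em@x, em@y)))
  diag(d) <- Inf
  nn <- mean(apply(d, 1, min))
  expected <- 0.5 / sqrt(400 / 6)
  expect_equal(nn, expected, tolerance = 0.15)
})

test_that("jittered-grid samples respect their separation guarantee", {
  em <- isolatedEmitterSample(20, 5.9, seed = 4)
  d <- as.matrix(dist(cbind(em@x, em@y)))
  diag(d) <- Inf
  g <- ceiling(sqrt(20))
  cell <- (5.9 - 0.6) / g
  expect_gte(min(d), (1 - 2 * 0.15) * cell - 1e-9)
})

test_that("bleaching decays expectations geometrically", {
  expect_equal(applyBleaching(c(4, 4, 4), 0), c(4, 4, 4))
  expect_equal(applyBleaching(c(1, 1, 1), log(2)), c(1, 0.5, 0.25))
  # total expected signal approaches the geometric sum
  r <- 0.05
  x <- applyBleaching(rep(1, 2000), r)
  expect_equal(sum(x), 1 / (1 - exp(-r)), tolerance = 1e-6)
  # matrix form scales columns (frames)
  m <- applyBleaching(matrix(1, 2, 3), log(2))
  expect_equal(m, cbind(c(1, 1), c(0.5, 0.5), c(0.25, 0.25)))
})
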