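test_that("mean image equals brute-force frame averaging", {
  expect_equal(meanImage(traceStack(rep(3.5, 6)))[1, 1], 3.5)
  expect_equal(meanImage(traceStack(c(0, 10, 0, 10)))[1, 1], 5)
  set.seed(1)
  fr <- array(rnorm(5 * 4 * 7), c(5, 4, 7))
  st <- frameStack(fr)
  acc <- matrix(0, 5, 4)
  for (t in 1:7) acc <- acc + fr[, , t]
  expect_equal(meanImage(st), acc / 7)
})

test_that("order-2 cumulant matches its defining formulas", {
  expect_equal(as.matrix(cumulant2(traceStack(rep(2, 10))))[1, 1], 0)
  expect_equal(as.matrix(cumulant2(traceStack(c(0, 10, 0, 10))))[1, 1],
               100 / 3)
  # lag-1 on the alternating trace: products all -25, divisor n-2
  expect_equal(as.matrix(cumulant2(traceStack(c(0, 10, 0, 10)), lag = 1))[1, 1],
               3 * (-25) / 2)
  expect_error(cumulant2(traceStack(c(1, 2)), lag = 1), "at least")
})

test_that("order-3 cumulant is the unbiased k3", {
  expect_equal(as.matrix(cumulant3(traceStack(c(0, 10, 0, 10))))[1, 1], 0)
  expect_equal(as.matrix(cumulant3(traceStack(c(0, 0, 10))))[1, 1],
               3 * (6000 / 27) / 2)
  expect_error(cumulant3(traceStack(c(1, 2))), "at least 3")
})

test_that("cumulants equal an independent moment-formula oracle on short traces", {
  set.seed(20)
  for (rep in 1:8) {
    n <- sample(5:20, 1)
    x <- round(runif(n, 0, 50))
    st <- traceStack(x)
    expect_equal(as.matrix(cumulant2(st))[1, 1], oracleCumulant2(x))
    expect_equal(as.matrix(cumulant2(st, lag = 1))[1, 1],
                 oracleCumulant2(x, lag = 1))
    expect_equal(as.matrix(cumulant3(st))[1, 1], oracleCumulant3(x))
  }
})

test_that("cumulants are offset-invariant and scale as c^2 / c^3", {
  set.seed(30)
  fr <- array(rpois(8 * 8 * 50, 20), c(8, 8, 50))
  st <- frameStack(fr)
  stOff <- frameStack(fr + 123.456)  # constant background added to every frame
  expect_equal(as.matrix(cumulant2(stOff)), as.matrix(cumulant2(st)))
  expect_equal(as.matrix(cumulant2(stOff, lag = 2)),
               as.matrix(cumulant2(st, lag = 2)))
  expect_equal(as.matrix(cumulant3(stOff)), as.matrix(cumulant3(st)))
  cs <- frameStack(fr * 3)
  expect_equal(as.matrix(cumulant2(cs)), 9 * as.matrix(cumulant2(st)))
  expect_equal(as.matrix(cumulant3(cs)), 27 * as.matrix(cumulant3(st)))
})

test_that("a pure-Poisson pixel has lag-0 variance ~ mean and lag-1 ~ 0", {
  set.seed(40)
  n <- 10000
  lam <- 30
  x <- rpois(n, lam)
  st <- traceStack(x)
  # var(s^2) for Poisson ~ (mu4 - sigma^4)/n, mu4 = lam(1 + 3 lam)
  seVar <- sqrt((lam * (1 + 3 * lam) - lam^2) / n)
  expect_lt(abs(as.matrix(cumulant2(st))[1, 1] - lam), 3 * seVar)
  # lag-1 autocovariance of iid draws: SE ~ sigma^2/sqrt(n)
  expect_lt(abs(as.matrix(cumulant2(st, lag = 1))[1, 1]), 3 * lam / sqrt(n))
})

test_that("a two-state pixel converges to A^2 p (1-p) variance and Bernoulli k3", {
  set.seed(50)
  n <- 10000
  A <- 10
  # iid Bernoulli(0.3) trace via transition probabilities summing to 1
  tr <- A * simulateBlinkTraces(blinkKinetics(pOnToOff = 0.7, pOffToOn = 0.3),
                                1, n)
  v <- as.matrix(cumulant2(traceStack(as.numeric(tr))))[1, 1]
  p <- 0.3
  mu2 <- A^2 * p * (1 - p)
  mu4 <- p * (A - A * p)^4 + (1 - p) * (A * p)^4
  seVar <- sqrt((mu4 - mu2^2) / n)
  expect_lt(abs(v - mu2), 3 * seVar)
  # symmetric Bernoulli (p = 0.5): third cumulant is 0; asymptotic
  # var(k3) ~ (mu6 - 6 mu2 mu4 + 9 mu2^3)/n with deviations +/- A/2
  tr5 <- A * simulateBlinkTraces(blinkKinetics(0.5, 0.5), 1, n)
  k3 <- as.matrix(cumulant3(traceStack(as.numeric(tr5))))[1, 1]
  d <- A / 2
  seK3 <- sqrt((d^6 - 6 * d^2 * d^4 + 9 * d^6) / n)
  expect_lt(abs(k3), 3 * seK3)
})

test_that("z-stack cumulants follow the per-plane computation and peak at focus", {
  em <- flatLayerSample(25, 1.8, brightness = 2000, seed = 61)
  plan <- acquisitionPlan(nFrames = 120, frameShape = c(40, 40),
                          zPositionsUm = seq(-0.6, 0.6, 0.3), seed = 62)
  ser <- simulateZScan(em, plan, defaultPsf(), blinkKinetics(), cameraModel())
  cums <- sofiZStack(ser, order = 2, lag = 0)
  expect_length(cums, 5)
  expect_equal(as.matrix(cums[[2]]), as.matrix(cumulant2(ser[[2]])))
  sums <- vapply(cums, function(ci) sum(as.matrix(ci)), numeric(1))
  expect_equal(which.max(sums), 3L)  # focal plane
  # constant stacks give all-zero cumulant images
  const <- zScanSeries(c(0, 1), list(frameStack(array(5, c(4, 4, 10))),
                                     frameStack(array(9, c(4, 4, 10)))))
  zeroes <- sofiZStack(const)
  expect_equal(as.matrix(zeroes[[1]]), matrix(0, 4, 4))
  expect_equal(as.matrix(zeroes[[2]]), matrix(0, 4, 4))
})

test_that("fluctuation diagnostic separates blinking from bleaching", {
  # stationary blinking: trend fraction near 0
  set.seed(70)
  tr <- 50 * simulateBlinkTraces(blinkKinetics(0.2, 0.2), 1, 1000)
  rep1 <- fluctuationDiagnostic(traceStack(as.numeric(tr)))
  expect_lt(rep1@medianFraction, 0.05)
  expect_identical(verdict(rep1), "fluctuation-dominated")
  # strictly linear decay: trend fraction 1
  rep2 <- fluctuationDiagnostic(traceStack(seq(100, 1, length.out = 100)))
  expect_equal(rep2@medianFraction, 1)
  expect_identical(verdict(rep2), "trend-dominated")
  # dense blinking layer with exponential bleaching at 0.01/frame over 300
  # frames: bright pixels become trend-dominated
  em <- flatLayerSample(120, 1.4, brightness = 1200, seed = 71)
  plan <- acquisitionPlan(nFrames = 300, frameShape = c(32, 32), seed = 72)
  st <- simulateMovie(em, plan, defaultPsf(), blinkKinetics(), cameraModel(),
                      bleachRatePerFrame = 0.01)
  rep3 <- fluctuationDiagnostic(st, minMean = 20)
  expect_identical(verdict(rep3), "trend-dominated")
  # the same sample without bleaching stays fluctuation-dominated
  st0 <- simulateMovie(em, plan, defaultPsf(), blinkKinetics(), cameraModel())
  expect_identical(verdict(fluctuationDiagnostic(st0, minMean = 20)),
                   "fluctuation-dominated")
})
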