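# per-neuron estimation of sigma, A and tau

test_that("sigma estimation recovers the white-noise SD and applies the
          profile bias", {
  x <- fluoTrace(1 + 0.02 * genNoise("white", 6000, 0.01, seed = 11),
                 rate = 100)
  expect_equal(estimateSigma(x), 0.02, tolerance = 0.03)
  expect_equal(estimateSigma(x, profile = probeProfile("ogb")),
               0.7 * 0.02, tolerance = 0.03)
  expect_equal(estimateSigma(x, profile = probeProfile("gcamp6s")),
               0.02, tolerance = 0.03)
  # out-of-band signal contributes nothing
  tgrid <- (0:5999) * 0.01
  slow <- fluoTrace(1 + 0.5 * sin(2 * pi * 0.5 * tgrid), rate = 100)
  expect_lt(estimateSigma(slow), 0.01)
  # scale equivariance
  x5 <- fluoTrace(5 * traceValues(x), rate = 100)
  expect_equal(estimateSigma(x5), 5 * estimateSigma(x), tolerance = 1e-9)
  expect_warning(estimateSigma(fluoTrace(rnorm(500), rate = 30)),
                 "Nyquist")
  expect_error(estimateSigma(fluoTrace(rnorm(10), rate = 100)), "short")
})

test_that("event detection finds isolated transients of arbitrary
          amplitude", {
  p <- modelParams(A = 0.06, tau = 0.8, sigma = 0, lam = 0.1)
  sim <- simulateTrace(spikeTrain(2), p, 6, 0.01)
  # noiseless data: drift-free working model (with a flexible baseline
  # and a tiny sigma, amplitudes are only identified up to slow drift)
  wp <- workingParams(sigma = 0.005, eta = 0)
  ctl <- spikeControl(nc = 50, nb = 1, cmax = 6, baseline = 1)
  ev <- detectEvents(sim$trace, wp, control = ctl)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$time - 2), 0.02)
  expect_lt(abs(ev$amplitude - 0.06), 0.01)
  # flat trace: nothing
  flat <- fluoTrace(rep(1, 600), dt = 0.01)
  expect_equal(nrow(detectEvents(flat, wp, control = ctl)), 0)
  # two transients 0.5 s apart resolve as two events
  sim2 <- simulateTrace(spikeTrain(c(2, 2.5)), p, 6, 0.01)
  ev2 <- detectEvents(sim2$trace, wp, control = ctl)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$time, c(2, 2.5), tolerance = 0.02)
})

test_that("isolation rules exclude close and large events and re-fit the
          kept ones", {
  p <- modelParams(A = 0.06, tau = 0.8, sigma = 0, lam = 0.1)
  wp <- workingParams(sigma = 0.005)
  # events at 0.5 s spacing: both excluded
  ev <- data.frame(time = c(2, 2.5), amplitude = c(0.06, 0.06),
                   bin = c(201, 251), trial = c(1L, 1L))
  sim <- simulateTrace(spikeTrain(c(2, 2.5)), p, 6, 0.01)
  expect_null(selectIsolatedEvents(ev, sim$trace, wp))
  # a 30% event is excluded, an isolated 6% noiseless event re-fits
  # to its exact amplitude
  p2 <- modelParams(A = 0.06, tau = 0.8, sigma = 0, lam = 0.1, nmax = 5L)
  sim2 <- simulateTrace(spikeTrain(c(2, rep(8, 5))), p2, 12, 0.01)
  ev2 <- data.frame(time = c(2, 8), amplitude = c(0.06, 0.30),
                    bin = c(201, 801), trial = c(1L, 1L))
  sel <- selectIsolatedEvents(ev2, sim2$trace, wp)
  expect_equal(nrow(sel$events), 1)
  expect_equal(sel$events$amplitude, 0.06, tolerance = 1e-3)
  expect_equal(sel$tau, 0.8, tolerance = 0.01)
})

test_that("the amplitude histogram cost locates the unitary amplitude", {
  lin <- modelParams(probe = "linear")
  # amplitudes clustered at A and the 2-spike amplitude
  set.seed(13)
  amps <- c(rnorm(80, 0.06, 0.002), rnorm(30, 0.12, 0.003))
  AHat <- histogramCostA(amps, lin)
  expect_lt(abs(as.numeric(AHat) - 0.06), 0.005)   # within ~a bin width
  # single tight peak
  A2 <- histogramCostA(rnorm(50, 0.05, 0.001), lin)
  expect_lt(abs(as.numeric(A2) - 0.05), 0.005)
  expect_error(histogramCostA(numeric(0), lin), "empty")
  expect_error(histogramCostA(c(0.05, 0.06), lin), "at least 3")
  # the two-spike amplitude honors the nonlinearity
  expect_equal(multiSpikeAmplitude(0.06, 2, lin), 0.12)
  expect_lt(multiSpikeAmplitude(0.06, 2, ogbParams()), 0.12)
})

test_that("spike counts are assigned at (k + 0.3) A separations", {
  lin <- modelParams(probe = "linear")
  # separations at 0.3A, 1.3A, 2.3A, ...
  expect_equal(assignSpikeCounts(c(1.0, 1.5, 0.2, 2.4) * 0.05, 0.05, lin),
               c(1L, 2L, 0L, 3L))
  # monotone in amplitude
  a <- seq(0.001, 0.4, by = 0.001)
  k <- assignSpikeCounts(a, 0.05, lin)
  expect_true(all(diff(k) >= 0))
  # nonlinear generalization: separations track multi-spike amplitudes
  sat <- ogbParams()
  kSat <- assignSpikeCounts(0.05 * probeResponse(3, sat), 0.05, sat)
  expect_equal(kSat, 3L)
})

test_that("final calibration recovers A and tau from noiseless data", {
  p <- modelParams(A = 0.05, tau = 0.8, sigma = 0, lam = 0.1)
  sim <- simulateTrace(spikeTrain(c(2, 6)), p, 10, 0.01)
  fit <- calibrateATau(sim$trace, list(c(2, 6)), list(c(1L, 1L)),
                       modelParams(probe = "linear"),
                       init = c(0.08, 0.5))
  expect_equal(unname(fit["A"]), 0.05, tolerance = 1e-3)
  expect_equal(unname(fit["tau"]), 0.8, tolerance = 1e-3)
  expect_error(calibrateATau(sim$trace, list(numeric(0)), list(integer(0)),
                             p), "no assigned")
})

test_that("single-exponential fitting is exact on exact data and
          reproduces the two-exponential reduction", {
  tgrid <- seq(0, 5, by = 0.001)
  fit <- fitSingleExponential(tgrid, 3 * exp(-tgrid / 0.5))
  expect_equal(unname(fit["amplitude"]), 3, tolerance = 1e-9)
  expect_equal(unname(fit["tau"]), 0.5, tolerance = 1e-9)
  z <- fitSingleExponential(tgrid, rep(0, length(tgrid)))
  expect_equal(unname(z["amplitude"]), 0)
  expect_warning(fitSingleExponential(tgrid, tgrid), "boundary")
  # the OGB literature transient: 7.7% e^{-t/56ms} + 3.1% e^{-t/777ms}
  y <- 7.7 * exp(-tgrid / 0.056) + 3.1 * exp(-tgrid / 0.777)
  lit <- fitSingleExponential(tgrid, y)
  expect_equal(unname(lit["amplitude"]), 6.27, tolerance = 0.05 * 6.27)
  expect_equal(unname(lit["tau"]), 0.366, tolerance = 0.05 * 0.366)
})

test_that("autocalibration recovers parameters on clean data and falls
          back gracefully on pure noise", {
  set.seed(17)
  p <- modelParams(A = 0.06, tau = 0.9, probe = "saturating", gamma = 0.1,
                   sigma = 0.008, lam = 0.2)
  traces <- lapply(1:3, function(k) {
    train <- genBurstyTrain(0.25, 30, seed = 44 + k)
    simulateTrace(train, p, 30, 0.01, seed = 47 + k)$trace
  })
  calib <- autocalibrate(traces, probeProfile("ogb"))
  expect_false(calib@fallback)
  expect_lt(abs(calib@AHat - 0.06), 0.015)
  expect_lt(abs(calib@tauHat - 0.9), 0.2)
  # pure noise: flagged fallback with profile defaults
  noise <- fluoTrace(1 + 0.01 * genNoise("white", 3000, 0.01, seed = 46),
                     rate = 100)
  expect_warning(fb <- autocalibrate(list(noise), probeProfile("ogb")),
                 "fallback")
  expect_true(fb@fallback)
  expect_equal(fb@AHat, probeProfile("ogb")@A)
  # calibrated parameter export
  pp <- calibratedParams(calib, probeProfile("ogb"))
  expect_equal(pp@A, calib@AHat)
  expect_equal(pp@sigma, calib@sigmaHat[1])
})
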