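# forward model: calcium evolution, probe nonlinearities, measurement,
# trace simulation

test_that("calcium evolution decays first, then adds spikes", {
  expect_equal(evolveCalcium(0, 1, 0.01, 1), 1.0)
  expect_equal(evolveCalcium(1, 0, 1, 1), exp(-1))
  expect_equal(evolveCalcium(0.5, 2, 0.01, 1), 0.5 * exp(-0.01) + 2)
  # vectorized
  expect_equal(evolveCalcium(c(0, 1), c(1, 0), 0.5, 2),
               c(1, exp(-0.25)))
  expect_error(evolveCalcium(0, -1, 0.01, 1), "non-negative")
  expect_error(evolveCalcium(0, 0.5, 0.01, 1), "integer")
})

test_that("all probe responses are normalized to g(0)=0, g(1)=1", {
  probes <- list(
    modelParams(probe = "linear"),
    ogbParams(),
    gcamp6sParams(),
    modelParams(probe = "hill", gamma = 0.1, nHill = 2, c0 = 0.3),
    modelParams(probe = "hill_rise", gamma = 0.1, nHill = 2, c0 = 0.3)
  )
  for (p in probes) {
    expect_equal(probeResponse(0, p), 0)
    expect_equal(probeResponse(1, p), 1)
    # monotone increasing over the physiological range (the fitted cubic
    # of the polynomial probe eventually turns over, around c ~ 10 for
    # the GCaMP6s coefficients, beyond its domain of validity)
    g <- probeResponse(seq(0, 8, by = 0.05), p)
    expect_true(all(diff(g) > 0))
  }
})

test_that("saturating probe reaches half its asymptote at 1/gamma spikes", {
  p <- ogbParams()  # gamma = 0.1
  asymptote <- (1 + p@gamma) / p@gamma
  half <- uniroot(function(c) probeResponse(c, p) - asymptote / 2,
                  c(1e-6, 1e6), tol = 1e-12)$root
  expect_equal(half, 1 / p@gamma, tolerance = 1e-9)
})

test_that("GCaMP6s polynomial evaluates as its cubic", {
  p <- gcamp6sParams()
  expect_equal(probeResponse(2, p), 0.32 * 2 + 0.73 * 4 - 0.05 * 8)
})

test_that("hill probe with n = 1, c0 = 0 is the saturating probe", {
  h <- modelParams(probe = "hill", gamma = 0.1, nHill = 1, c0 = 0)
  s <- ogbParams()
  cgrid <- seq(0, 50, by = 0.1)
  expect_lt(max(abs(probeResponse(cgrid, h) - probeResponse(cgrid, s))),
            1e-12)
})

test_that("bound-probe evolution: fixed point, tauOn = 0 reduction, and a
          sub-stepped integration oracle", {
  p <- modelParams(probe = "hill_rise", gamma = 0.1, nHill = 2, c0 = 0.1,
                   tauOn = 0.05)
  g1 <- probeResponse(1, p)
  # instantaneous binding recovers g exactly
  p0 <- p; p0@tauOn <- 0
  expect_equal(evolveProbe(0.3, 1, 0.01, p0), g1)
  # steady state is a fixed point
  expect_equal(evolveProbe(g1, 1, 0.02, p), g1)
  # one coarse step equals many fine steps with constant calcium (the exact
  # exponential relaxation); oracle: explicit Euler at dt/1000
  pFine <- p
  x <- 0
  nSub <- 10000
  h <- p@tauOn / nSub
  for (k in seq_len(nSub)) x <- x + (h / p@tauOn) * (g1 - x)
  coarse <- evolveProbe(0, 1, p@tauOn, p)
  expect_equal(coarse, (1 - exp(-1)) * g1, tolerance = 1e-12)
  expect_equal(x, coarse, tolerance = 1e-4)
  # stability for dt >> tauOn: stays within [0, g]
  expect_lt(evolveProbe(0, 1, 10 * p@tauOn, p), g1 + 1e-12)
})

test_that("measurement multiplies the baseline into the response", {
  p <- modelParams(A = 0.1)
  expect_equal(measureFluo(0, 1, p), 1)
  expect_equal(measureFluo(1, 1, p), 1.1)
  expect_equal(measureFluo(1, 0.9, p), 0.99)
})

test_that("noiseless simulation matches the closed-form transient", {
  s <- linearSim(times = 1, A = 0.1, tau = 1)
  v <- traceValues(s$sim$trace)
  tgrid <- (seq_along(v) - 1) * 0.01
  after <- tgrid >= 1.0
  expected <- ifelse(after, 1 + 0.1 * exp(-(tgrid - 1.0) / 1), 1)
  expect_lt(max(abs(v - expected)), 1e-12)
})

test_that("simultaneous spikes through a saturating probe are sub-linear", {
  p <- ogbParams(sigma = 0)
  sim <- simulateTrace(spikeTrain(c(1, 1)), p, 3, 0.01)
  peak <- max(traceValues(sim$trace)) - 1
  expect_equal(peak, p@A * (1.1 * 2 / 1.2), tolerance = 1e-12)
  expect_lt(peak, 2 * p@A)
})

test_that("simulation is deterministic given the seed", {
  p <- modelParams(A = 0.1, sigma = 0.05, eta = 0.01)
  s1 <- simulateTrace(spikeTrain(1), p, 3, 0.01, seed = 42)
  s2 <- simulateTrace(spikeTrain(1), p, 3, 0.01, seed = 42)
  s3 <- simulateTrace(spikeTrain(1), p, 3, 0.01, seed = 43)
  expect_identical(traceValues(s1$trace), traceValues(s2$trace))
  expect_false(identical(traceValues(s1$trace), traceValues(s3$trace)))
})

test_that("onset delay shifts the transient by the profile delay", {
  p <- gcamp6sParams(sigma = 0)  # 20 ms delay
  sim <- simulateTrace(spikeTrain(1), p, 3, 0.01)
  v <- traceValues(sim$trace)
  riseBin <- which(v > 1)[1]
  # spike at 1 s + 20 ms delay -> first elevated frame at 1.02 s
  expect_equal((riseBin - 1) * 0.01, 1.02)
})

test_that("spikes outside the duration are rejected", {
  p <- modelParams()
  expect_error(simulateTrace(spikeTrain(10), p, 5, 0.01), "duration")
})

test_that("parameter validity is enforced", {
  expect_error(modelParams(A = -1), "A")
  expect_error(modelParams(tau = 0), "tau")
  expect_error(modelParams(probe = "unknown"), "probe")
  expect_error(modelParams(nmax = 0), "nmax")
})
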