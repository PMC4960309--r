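# spike matching, error rates, correlation, noise level, PMT gain

test_that("matching respects the tolerance as the break-even radius", {
  m <- matchSpikes(1.0, 1.4, 0.5)
  expect_equal(nrow(m@pairs), 1)
  expect_equal(m@nMiss, 0L)
  expect_equal(m@nFalse, 0L)
  m2 <- matchSpikes(1.0, 1.6, 0.5)
  expect_equal(nrow(m2@pairs), 0)
  expect_equal(m2@nMiss, 1L)
  expect_equal(m2@nFalse, 1L)
  m3 <- matchSpikes(c(1.0, 1.1), 1.05, 0.5)
  expect_equal(nrow(m3@pairs), 1)
  expect_equal(m3@nMiss, 1L)
})

test_that("matching equals exhaustive min-cost assignment on small
          instances", {
  # brute force: enumerate order-preserving one-to-one assignments
  bruteCost <- function(s, e, tol) {
    best <- Inf
    n <- length(s); m <- length(e)
    rec <- function(i, j, cost) {
      if (cost >= best) return()
      if (i > n && j > m) { best <<- min(best, cost); return() }
      if (i > n) { best <<- min(best, cost + (m - j + 1)); return() }
      if (j > m) { best <<- min(best, cost + (n - i + 1)); return() }
      d <- 2 * abs(s[i] - e[j]) / tol
      if (d <= 2) rec(i + 1, j + 1, cost + d)
      rec(i + 1, j, cost + 1)
      rec(i, j + 1, cost + 1)
    }
    rec(1, 1, 0)
    best
  }
  for (case in 1:30) {
    set.seed(case)
    s <- sort(runif(sample(0:6, 1), 0, 10))
    e <- sort(runif(sample(0:6, 1), 0, 10))
    m <- matchSpikes(s, e, 0.5)
    cost <- 2 * sum(abs(m@pairs[, 1] - m@pairs[, 2])) / 0.5 +
      m@nMiss + m@nFalse
    expect_equal(cost, bruteCost(s, e, 0.5), tolerance = 1e-9)
    # matched pairs within tolerance (class invariant)
    expect_true(validObject(m))
  }
})

test_that("error rate is 1 minus the F1 score, pooled over trials", {
  perfect <- matchSpikes(c(1, 2, 3), c(1, 2, 3), 0.5)
  expect_equal(errorRate(perfect), 0)
  # sens 1, prec 0.5 -> ER = 1/3
  m <- matchSpikes(c(1, 5), c(1, 3, 5, 7), 0.5)
  st <- errorStats(m)
  expect_equal(unname(st["sensitivity"]), 1)
  expect_equal(unname(st["precision"]), 0.5)
  expect_equal(unname(st["er"]), 1 / 3)
  # 9 matched, 1 miss, 0 false -> 1 - 18/19
  m2 <- matchSpikes(1:10, 1:9, 0.5)
  expect_equal(errorRate(m2), 1 - 18 / 19)
  # pooling adds counts before the rates
  pooled <- errorStats(list(m, m2))
  expect_equal(unname(pooled["sensitivity"]), (2 + 9) / (2 + 10))
  # both empty: ER = 0 flagged
  e <- errorStats(matchSpikes(numeric(0), numeric(0), 0.5))
  expect_equal(unname(e["er"]), 0)
  expect_true(attr(e, "degenerate"))
})

test_that("ER is symmetric and bounded below by the mean of miss and
          false rates", {
  for (case in 1:20) {
    set.seed(case)
    s <- sort(runif(sample(1:8, 1), 0, 10))
    e <- sort(runif(sample(1:8, 1), 0, 10))
    expect_equal(errorRate(matchSpikes(s, e, 0.5)),
                 errorRate(matchSpikes(e, s, 0.5)), tolerance = 1e-12)
    st <- errorStats(matchSpikes(s, e, 0.5))
    missRate <- 1 - st["sensitivity"]
    falseRate <- 1 - st["precision"]
    expect_gte(st["er"] + 1e-12, (missRate + falseRate) / 2)
  }
})

test_that("temporal error averages matched |delays|", {
  m <- matchSpikes(c(1, 2), c(1.01, 1.97), 0.5)
  expect_equal(meanTemporalError(m), 0.02)
  expect_lte(meanTemporalError(m), 0.5)
  expect_warning(meanTemporalError(matchSpikes(1, 10, 0.5)), "no matched")
})

test_that("rate correlation behaves on exact, shifted and empty estimates", {
  tr <- genPoissonTrain(2, 60, seed = 5)
  expect_equal(rateCorrelation(tr, tr), 1, tolerance = 1e-9)
  shifted <- spikeTrain(spikeTimes(tr) + 0.04)
  expect_lt(rateCorrelation(tr, shifted, duration = 60),
            rateCorrelation(tr, tr, duration = 60))
  expect_warning(r <- rateCorrelation(tr, spikeTrain(numeric(0)),
                                      duration = 60), "zero-variance")
  expect_true(is.na(r))
  # affine invariance for rate-series input
  rate <- rep(c(0, 1, 3), length.out = 600)
  r1 <- rateCorrelation(tr, rate, estDt = 0.1, duration = 60)
  r2 <- rateCorrelation(tr, 5 * rate + 2, estDt = 0.1, duration = 60)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("noise level is the band RMS of the residual over A'", {
  dt <- 0.01
  resid <- 0.02 * genNoise("white", 2^14, dt, seed = 6)
  pred <- rep(1, 2^14)
  lv <- noiseLevel(pred + resid, pred, APrime = 0.05, dt = dt)
  expect_equal(lv, 0.02 * sqrt(2 * 2.9 / 100) / 0.05, tolerance = 0.1)
  expect_equal(noiseLevel(pred, pred, 0.05, dt = dt), 0)
  expect_equal(noiseLevel(pred + 2 * resid, pred, 0.05, dt = dt), 2 * lv,
               tolerance = 1e-12)
  expect_error(noiseLevel(pred, pred, 0, dt = dt), "APrime")
})

test_that("A' is half the two-spike response (supra or sub linear)", {
  expect_equal(computeAPrime(modelParams(A = 0.1, probe = "linear")), 0.1)
  expect_equal(computeAPrime(ogbParams()), 0.1 * (1.1 * 2 / 1.2) / 2)
  expect_lt(computeAPrime(ogbParams()), 0.1)
  p6s <- gcamp6sParams()
  expect_equal(computeAPrime(p6s), 0.1 * 3.16 / 2)
  expect_gt(computeAPrime(p6s), 0.1)
  # GCaMP5k profile: 1/15 of the 15-spike response
  p5k <- probeProfile("gcamp5k")
  expect_equal(computeAPrime(p5k),
               p5k@A * probeResponse(15, p5k) / 15)
})

test_that("photonic gain is recovered from high-passed bead signals", {
  # Poisson photon counts, gain 2, mean N = 100 photons per bin
  set.seed(8)
  n <- 2^15
  bead <- 2 * stats::rpois(n, 100)
  g <- photonicGain(bead, fs = 1000, fc = 200)
  expect_equal(g, 2, tolerance = 0.05)
  # variance-recovery factor from the flat spectrum
  expect_equal((1000 / 2) / (1000 / 2 - 200), 5 / 3)
  expect_equal(photonicGain(rep(5, 1000), fs = 1000, fc = 200), 0)
  expect_error(photonicGain(rep(-1, 1000), fs = 1000, fc = 200),
               "positive")
  # band RMS of the photonic part
  expect_equal(photonicBandRMS(2, 100, 1000, c(0.1, 3)),
               sqrt(2 * 100 * 2 * 2.9 / 1000))
})
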