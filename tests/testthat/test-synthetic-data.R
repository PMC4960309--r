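# spike-train generators, noise generators and band-RMS calibration

test_that("Poisson train has the right moments and exponential intervals", {
  expect_equal(nSpikes(genPoissonTrain(0, 10, seed = 1)), 0)
  tr <- genPoissonTrain(1, 10000, seed = 2)
  expect_lt(abs(nSpikes(tr) - 10000), 3 * sqrt(10000))
  isi <- diff(spikeTimes(tr))
  ks <- suppressWarnings(stats::ks.test(isi, "pexp", rate = 1))
  expect_gt(ks$p.value, 0.01)
  # reproducible / seed-sensitive
  expect_identical(spikeTimes(genPoissonTrain(1, 50, seed = 7)),
                   spikeTimes(genPoissonTrain(1, 50, seed = 7)))
  expect_false(identical(nSpikes(genPoissonTrain(5, 50, seed = 7)),
                         nSpikes(genPoissonTrain(5, 50, seed = 8))))
})

test_that("bursty trains average one spike per event with 10 ms intervals", {
  expect_equal(nSpikes(genBurstyTrain(0, 10, seed = 1)), 0)
  # mean spikes per event: geometric with mean 1 over many events
  tr <- genBurstyTrain(100, 1000, seed = 3)  # ~1e5 events
  nev <- withr::with_seed(3L, stats::rpois(1, 100 * 1000))
  expect_equal(nSpikes(tr) / nev, 1.0, tolerance = 0.02)
  # within-burst intervals ~10 ms
  tr2 <- genBurstyTrain(2, 5000, seed = 4)
  isi <- diff(spikeTimes(tr2))
  burst <- isi[isi < 0.05]
  expect_gt(length(burst), 1000)
  expect_equal(mean(burst), 0.010, tolerance = 0.1)
})

test_that("noise generators have unit variance and the right spectra", {
  slope <- function(kind) {
    ss <- numeric(40)
    for (s in seq_len(40)) {
      x <- genNoise(kind, 8192, 0.01, seed = s)
      n <- length(x)
      X <- Mod(stats::fft(x))^2 / n
      f <- (seq_len(n) - 1) / (n * 0.01)
      keep <- f >= 0.1 & f <= 10
      ss[s] <- stats::coef(stats::lm(log(X[keep]) ~ log(f[keep])))[2]
    }
    mean(ss)
  }
  expect_equal(stats::var(genNoise("white", 4096, 0.01, seed = 1)), 1,
               tolerance = 1e-12)
  expect_equal(stats::var(genNoise("pink", 4096, 0.01, seed = 1)), 1,
               tolerance = 1e-12)
  expect_equal(stats::var(genNoise("white_plus_drift", 4096, 0.01,
                                   seed = 1)), 1, tolerance = 1e-12)
  expect_equal(slope("white"), 0, tolerance = 0.1)
  expect_equal(slope("pink"), -1, tolerance = 0.1)
  expect_error(genNoise("blue", 100, 0.01), "arg")
})

test_that("band RMS is Parseval-consistent", {
  dt <- 0.01
  n <- 2^14
  tgrid <- (seq_len(n) - 1) * dt
  sine <- 0.5 * sin(2 * pi * 1 * tgrid)
  expect_equal(bandRMS(sine, dt, c(0.1, 3)), 0.5 / sqrt(2),
               tolerance = 0.02)
  # out of band: only spectral leakage remains (< 1% of the in-band RMS)
  expect_lt(bandRMS(sine, dt, c(5, 10)), 0.01 * 0.5 / sqrt(2))
  # white noise: sigma * sqrt(2 (f2 - f1) / fs), averaged over seeds
  r <- mean(vapply(1:30, function(s)
    bandRMS(0.02 * genNoise("white", n, dt, seed = s), dt, c(0.1, 3)), 0))
  expect_equal(r, 0.02 * sqrt(2 * 2.9 / 100), tolerance = 0.05)
  expect_error(bandRMS(sine, dt, c(0.1, 80)), "Nyquist")
})

test_that("noise scaling hits the requested level exactly and is
          homogeneous", {
  x <- genNoise("pink", 4096, 0.01, seed = 9)
  y <- scaleNoiseToLevel(x, 0.2, 0.1, 0.01)
  expect_equal(bandRMS(y, 0.01, c(0.1, 3)) / 0.1, 0.2, tolerance = 1e-9)
  y2 <- scaleNoiseToLevel(x, 0.4, 0.1, 0.01)
  expect_equal(y2, 2 * y, tolerance = 1e-12)
  expect_equal(scaleNoiseToLevel(x, 0, 0.1, 0.01), numeric(4096))
})

test_that("pink noise concentrates its power in the 0.1-3 Hz band", {
  # at equal total variance (SNR), pink noise has a higher band-RMS noise
  # level than white; equivalently, scaled to the same band level, pink
  # carries less total variance
  w <- genNoise("white", 8192, 0.01, seed = 2)
  p <- genNoise("pink", 8192, 0.01, seed = 2)
  expect_gt(bandRMS(p, 0.01), bandRMS(w, 0.01))   # equal variance here
  ws <- scaleNoiseToLevel(w, 0.1, 0.1, 0.01)
  ps <- scaleNoiseToLevel(p, 0.1, 0.1, 0.01)
  expect_lt(stats::var(ps), stats::var(ws))
})
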