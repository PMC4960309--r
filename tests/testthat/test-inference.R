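# grid inference engine: probabilities, MAP decoding, smoothing, sampling

test_that("transition log probability is truncated Poisson plus Gaussian
          baseline step", {
  p <- modelParams(lam = 0.1, eta = 0)
  expect_equal(transitionLogProb(0, 0, p, 0.01), -0.001)
  expect_equal(transitionLogProb(p@nmax + 1, 0, p, 0.01), -Inf)
  pd <- modelParams(lam = 0.1, eta = 0.05)
  expect_equal(transitionLogProb(1, 0.002, pd, 0.01),
               dpois(1, 0.001, log = TRUE) +
                 dnorm(0.002, 0, 0.05 * sqrt(0.01), log = TRUE))
})

test_that("emission log probability is the Gaussian density at the
          predicted fluorescence", {
  p <- modelParams(A = 0.1, sigma = 0.02)
  pred <- measureFluo(1, 1, p)
  expect_equal(emissionLogProb(pred, 1, 1, p), -log(0.02 * sqrt(2 * pi)))
  d <- 0.013
  expect_equal(emissionLogProb(pred + d, 1, 1, p),
               emissionLogProb(pred - d, 1, 1, p))
  # likelihood ratios follow the Gaussian density exactly
  lr <- emissionLogProb(1.05, 1, 1, p) - emissionLogProb(1.05, 0.5, 1, p)
  expect_equal(lr, dnorm(1.05, measureFluo(1, 1, p), 0.02, log = TRUE) -
                 dnorm(1.05, measureFluo(0.5, 1, p), 0.02, log = TRUE),
               tolerance = 1e-12)
  p0 <- modelParams(A = 0.1, sigma = 0)
  expect_equal(emissionLogProb(2, 1, 1, p0), -Inf)
})

test_that("noiseless single-spike trace decodes exactly", {
  s <- linearSim(times = 2, A = 0.1, tau = 1)
  p <- s$params
  p@sigma <- 0.005
  p@lam <- 0.5
  fit <- mapSpikes(s$sim$trace, p, spikeControl(nc = 60, nb = 30))
  expect_equal(nSpikes(fit), 1)
  expect_equal(spikeTimes(fit), 1.995)
  # baseline recovered up to its grid quantization (30 values over +/-30%)
  expect_lt(abs(mean(latentPath(fit)@baseline) - 1), 0.025)
})

test_that("a constant trace yields no spikes", {
  p <- modelParams(A = 0.1, sigma = 0.02, lam = 0.5)
  fit <- mapSpikes(fluoTrace(rep(1, 300), dt = 0.01), p,
                   spikeControl(nc = 50, nb = 20))
  expect_equal(nSpikes(fit), 0)
})

test_that("with dominant noise the prior wins and no spikes are called", {
  set.seed(31)
  p <- modelParams(A = 0.001, sigma = 0.5, lam = 0.1)
  y <- fluoTrace(1 + rnorm(200, 0, 0.5), dt = 0.01)
  fit <- mapSpikes(y, p, spikeControl(nc = 40, nb = 10))
  expect_equal(nSpikes(fit), 0)
})

test_that("an unknown flat baseline well below 1 is recovered", {
  s <- linearSim(times = c(1, 3), duration = 6)
  p <- s$params; p@sigma <- 0.01; p@lam <- 0.5
  sim <- simulateTrace(spikeTrain(c(1, 3)), p, 6, 0.01, baseline = 0.7)
  fit <- mapSpikes(sim$trace, p, spikeControl(nc = 60, nb = 60))
  B <- latentPath(fit)@baseline
  expect_equal(mean(B[100:600]), 0.7, tolerance = 0.02)
  expect_equal(nSpikes(fit), 2)
})

test_that("MAP agrees with exhaustive enumeration on small instances", {
  ctl <- oracleControl()
  for (i in 1:25) {
    inst <- oracleInstance(i)
    fit <- mapSpikes(inst$trace, inst$params, ctl)
    bf <- bruteForceMap(inst$trace, inst$params, c1Values = 0,
                        bValues = 1, nmax = 2)
    expect_identical(spikeCounts(fit), as.integer(bf$counts))
    expect_equal(logPosterior(fit), bf$logPosterior, tolerance = 1e-6)
  }
})

test_that("engine log posterior is at least that of the grid-projected
          truth, and spike counts respect nmax", {
  for (i in 1:10) {
    inst <- oracleInstance(i)
    fit <- mapSpikes(inst$trace, inst$params, oracleControl())
    expect_true(all(spikeCounts(fit) <= inst$params@nmax))
    # evaluate the true binned path under the same posterior
    bf <- bruteForceMap(inst$trace, inst$params, c1Values = 0,
                        bValues = 1, nmax = 2)
    expect_gte(logPosterior(fit) + 1e-9, bf$logPosterior)
  }
})

test_that("smoothed spike marginals match the exhaustive posterior and
          normalize", {
  ctl <- oracleControl()
  for (i in 1:10) {
    inst <- oracleInstance(i)
    post <- spikeProbabilities(inst$trace, inst$params, ctl)
    marg <- spikeMarginals(post)
    expect_lt(max(abs(rowSums(marg) - 1)), 1e-9)
    bfp <- bruteForcePosterior(inst$trace, inst$params, c1Values = 0,
                               bValues = 1, nmax = 2)
    expect_lt(max(abs(marg - bfp)), 1e-6)
  }
})

test_that("a noiseless well-separated spike has posterior mass 1 in its
          bin", {
  s <- linearSim(times = 2, duration = 4)
  p <- s$params; p@sigma <- 0.005; p@lam <- 0.5
  post <- spikeProbabilities(s$sim$trace, p, spikeControl(nc = 80, nb = 1,
                                                          baseline = 1))
  marg <- spikeMarginals(post)
  spikeBin <- 201  # spike at 2 s -> effect at frame ceil(2/dt) + 1 = 201
  expect_gt(marg[spikeBin, "n1"], 0.999)
  expect_lt(max(marg[-spikeBin, "n1"]), 1e-3)
})

test_that("filtering distributions normalize when kept", {
  inst <- oracleInstance(3)
  ctl <- oracleControl(nc = 100)
  ctl$keepArrays <- TRUE
  post <- spikeProbabilities(inst$trace, inst$params, ctl)
  a <- post@alpha
  sums <- apply(a, 3, sum)
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("posterior sampling is reproducible and consistent with the
          marginals", {
  p <- modelParams(A = 0.1, tau = 0.5, sigma = 0.04, lam = 1, nmax = 2L)
  sim <- simulateTrace(spikeTrain(c(0.5, 1.5, 1.55)), p, 3, 0.05, seed = 5)
  ctl <- spikeControl(nc = 200, nb = 1, cmax = 6, baseline = 1)
  s1 <- samplePosterior(sim$trace, p, ctl, nSamples = 50, seed = 21)
  s2 <- samplePosterior(sim$trace, p, ctl, nSamples = 50, seed = 21)
  expect_identical(s1$counts, s2$counts)
  post <- spikeProbabilities(sim$trace, p, ctl)
  smp <- samplePosterior(sim$trace, p, ctl, nSamples = 2000, seed = 22)
  marg <- spikeMarginals(post)
  for (k in 0:2)
    expect_lt(max(abs(rowMeans(smp$counts == k) - marg[, k + 1])), 0.05)
})

test_that("in the noiseless limit all samples equal the true train", {
  s <- linearSim(times = 2, duration = 4)
  p <- s$params; p@sigma <- 0.004; p@lam <- 0.5
  smp <- samplePosterior(s$sim$trace, p,
                         spikeControl(nc = 80, nb = 1, baseline = 1),
                         nSamples = 20, seed = 30)
  counts <- smp$counts
  expect_true(all(colSums(counts) == 1))
  expect_true(all(counts[201, ] == 1))
})

test_that("runtime grows about linearly with trace length", {
  p <- modelParams(A = 0.1, sigma = 0.03, lam = 0.5)
  ctl <- spikeControl(nc = 40, nb = 20)
  sim1 <- simulateTrace(genPoissonTrain(0.5, 10, seed = 1), p, 10, 0.01,
                        seed = 2)
  sim10 <- simulateTrace(genPoissonTrain(0.5, 100, seed = 1), p, 100,
                         0.01, seed = 2)
  t1 <- system.time(mapSpikes(sim1$trace, p, ctl))["elapsed"]
  t10 <- system.time(mapSpikes(sim10$trace, p, ctl))["elapsed"]
  expect_lt(t10, 12 * max(t1, 0.05))
})

test_that("degenerate inputs are rejected", {
  p <- modelParams(sigma = 0.02)
  expect_error(mapSpikes(fluoTrace(c(1, NA, 1), dt = 0.01), p), "finite")
  p0 <- modelParams(sigma = 0)
  expect_error(mapSpikes(fluoTrace(rep(1, 10), dt = 0.01), p0), "sigma")
  expect_error(bruteForceMap(fluoTrace(rep(1, 40), dt = 0.01), p,
                             nmax = 3), "maxPaths")
})

test_that("hill_rise inference decodes a clean transient", {
  p <- modelParams(A = 0.15, tau = 0.6, probe = "hill_rise", gamma = 0.1,
                   nHill = 2, c0 = 0.1, tauOn = 0.05, sigma = 0.01,
                   lam = 0.5)
  sim <- simulateTrace(spikeTrain(1), p, 3, 0.02)
  fit <- mapSpikes(sim$trace, p,
                   spikeControl(nc = 40, nb = 10, np = 25, cmax = 5))
  expect_equal(nSpikes(fit), 1)
  expect_equal(spikeTimes(fit), 0.99, tolerance = 0.05)
})
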