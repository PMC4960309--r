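# shared fixtures: small parameter sets and simulation shortcuts

ogbParams <- function(...) {
  modelParams(A = 0.1, tau = 1, probe = "saturating", gamma = 0.1, ...)
}

gcamp6sParams <- function(...) {
  modelParams(A = 0.1, tau = 1, probe = "polynomial", p2 = 0.73,
              p3 = -0.05, delay = 0.02, ...)
}

# a short noiseless trace with known spikes, linear probe
linearSim <- function(times = c(1, 2.5), A = 0.1, tau = 1, duration = 5,
                      dt = 0.01, ...) {
  p <- modelParams(A = A, tau = tau, sigma = 0, ...)
  sim <- simulateTrace(spikeTrain(times), p, duration, dt)
  list(params = p, sim = sim)
}

# engine configuration used for the small-instance oracle comparisons:
# fixed known baseline, resting start, dense calcium grid
oracleControl <- function(nc = 600, cmax = 8) {
  spikeControl(nc = nc, nb = 1, cmax = cmax, c1Prior = "rest", baseline = 1)
}

# random 12-bin instance of the generative model (fixed baseline at 1)
oracleInstance <- function(i, nmax = 2L) {
  set.seed(i)
  p <- modelParams(A = 0.1, tau = stats::runif(1, 0.3, 1),
                   sigma = stats::runif(1, 0.02, 0.06),
                   lam = stats::runif(1, 0.5, 2), nmax = nmax)
  train <- genPoissonTrain(p@lam, 1.1, seed = 100 + i)
  sim <- simulateTrace(train, p, 1.2, 0.1, seed = 200 + i)
  list(params = p, trace = sim$trace)
}
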