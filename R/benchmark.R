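#' @include infer.R metrics.R synth.R
NULL

#' Run the standard simulation benchmark
#'
#' Simulates Poisson-spiking trials with known generative parameters (flat
#' baseline whose level is not given to the algorithm, drawn uniformly per
#' trial), adds noise of a chosen spectral type scaled to a band-RMS noise
#' level, runs MAP inference with the generating parameters (noise SD set
#' to the realized SD of the generated noise; baseline recovered through
#' its uniform prior), and pools matched / missed / false spikes over
#' trials into a single error rate.
#'
#' @param nTrials number of trials.
#' @param duration trial duration (s).
#' @param dt frame interval (s).
#' @param rates spike-rate range (sp/s); trials sweep it uniformly.
#' @param level band-RMS noise level (units of A, 0.1--3 Hz band).
#' @param kind noise regime ("white", "white_plus_drift", "pink").
#' @param A,tau generative amplitude and decay constant.
#' @param control engine control settings.
#' @param seed integer seed; trial seeds are derived from it.
#' @param tolerance spike matching tolerance (s).
#' @param baselineRange range of the per-trial flat baseline level.
#' @param inferSigma noise SD given to the algorithm: \code{"realized"}
#'   (SD of the generated noise series, i.e. the true generative value) or
#'   \code{"estimate"} (3--20 Hz band estimate, no bias, plus a fixed
#'   working drift of 0.02 to absorb coloured noise).
#' @return a list with pooled \code{er}, \code{sensitivity},
#'   \code{precision}, \code{meanTemporalError}, \code{nTrue},
#'   \code{matches} (list of [MatchResult-class]).
#' @examples
#' \donttest{
#' runBenchmark(nTrials = 2, duration = 10, seed = 1)$er
#' }
#' @export
runBenchmark <- function(nTrials = 20, duration = 30, dt = 0.01,
                         rates = c(0.1, 1), level = 0.2, kind = "white",
                         A = 0.1, tau = 1, control = spikeControl(),
                         seed = 1, tolerance = 0.5,
                         baselineRange = c(0.85, 1.15),
                         inferSigma = c("realized", "estimate")) {
  inferSigma <- match.arg(inferSigma)
  seed <- as.integer(seed)
  p <- modelParams(A = A, tau = tau, lam = mean(rates))
  matches <- vector("list", nTrials)
  for (i in seq_len(nTrials)) {
    rate <- if (nTrials > 1)
      rates[1] + diff(rates) * (i - 1) / (nTrials - 1) else mean(rates)
    train <- genPoissonTrain(rate, duration, seed = seed * 1000L + i)
    B0 <- withr::with_seed(seed * 1000L + 500L + i,
                           stats::runif(1, baselineRange[1],
                                        baselineRange[2]))
    sim <- simulateTrace(train, p, duration, dt,
                         noise = noiseSpec(kind, level),
                         seed = seed * 1000L + 250L + i, baseline = B0)
    pi <- p
    pi@lam <- max(rate, 0.05)
    if (inferSigma == "realized") {
      pi@sigma <- stats::sd(sim$trace@values - sim$noiseless)
    } else {
      pi@sigma <- estimateSigma(sim$trace)
      pi@eta <- 0.02
    }
    fit <- mapSpikes(sim$trace, pi, control)
    matches[[i]] <- matchSpikes(train, fit, tolerance)
  }
  st <- errorStats(matches)
  list(er = unname(st["er"]), sensitivity = unname(st["sensitivity"]),
       precision = unname(st["precision"]),
       meanTemporalError = suppressWarnings(meanTemporalError(matches)),
       nTrue = sum(vapply(matches, function(m) nrow(m@pairs) + m@nMiss, 1L)),
       matches = matches)
}
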