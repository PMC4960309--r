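#' @include methods.R synth.R
NULL

#' Match two spike trains by minimum-cost alignment
#'
#' Order-preserving, one-to-one assignment between a reference ("true") and
#' an estimated spike train, computed by dynamic programming with
#' Victor-Purpura-style costs: matching two spikes a distance \eqn{|\Delta
#' t|} apart costs \eqn{2|\Delta t|/tol}, an unmatched spike (miss or false
#' detection) costs 1.  The tolerance is thus the exact break-even radius:
#' spikes further apart than \code{tolerance} are never matched.
#'
#' @param true reference spike train ([SpikeTrain-class] or numeric times).
#' @param est estimated spike train.
#' @param tolerance matching tolerance (s), default 0.5.
#' @return a [MatchResult-class].
#' @examples
#' matchSpikes(c(1.0), c(1.4), 0.5)   # one pair
#' matchSpikes(c(1.0), c(1.6), 0.5)   # one miss, one false
#' @export
matchSpikes <- function(true, est, tolerance = 0.5) {
  s <- spikeTimes(true); e <- spikeTimes(est)
  n <- length(s); m <- length(e)
  stopifnot(tolerance > 0)
  ## D[i+1, j+1]: min cost aligning s[1..i] with e[1..j]
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- 0:n
  D[1, ] <- 0:m
  if (n && m) {
    for (i in seq_len(n)) {
      shift <- 2 * abs(s[i] - e) / tolerance
      for (j in seq_len(m)) {
        cand <- c(D[i, j + 1] + 1, D[i + 1, j] + 1,
                  if (shift[j] <= 2) D[i, j] + shift[j] else Inf)
        D[i + 1, j + 1] <- min(cand)
      }
    }
  }
  ## traceback, preferring a match on ties (|dt| <= tolerance guaranteed)
  pairs <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("true", "est")))
  i <- n; j <- m
  while (i > 0 && j > 0) {
    shift <- 2 * abs(s[i] - e[j]) / tolerance
    if (shift <= 2 && abs(D[i, j] + shift - D[i + 1, j + 1]) < 1e-9) {
      pairs <- rbind(c(s[i], e[j]), pairs)
      i <- i - 1; j <- j - 1
    } else if (abs(D[i, j + 1] + 1 - D[i + 1, j + 1]) < 1e-9) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  new("MatchResult", pairs = pairs, nMiss = n - nrow(pairs),
      nFalse = m - nrow(pairs), tolerance = tolerance)
}

#' Sensitivity, precision and error rate of a matching
#'
#' The error rate (ER) is 1 minus the F1 score, i.e. 1 minus the harmonic
#' mean of sensitivity (matched / true) and precision (matched / estimated).
#' Passing a list of [MatchResult-class] objects pools the matched, missed
#' and falsely detected counts over trials before computing the rates,
#' yielding a single per-neuron figure.
#'
#' @param x a [MatchResult-class] or a list of them (pooled).
#' @return named numeric vector \code{c(sensitivity, precision, er)}.  When
#'   both trains are empty the ER is 0 by convention and the result carries
#'   the attribute \code{degenerate = TRUE}.
#' @examples
#' errorStats(matchSpikes(c(1, 2), c(1, 2.2), 0.5))
#' @export
errorStats <- function(x) {
  if (is(x, "MatchResult")) x <- list(x)
  nMatch <- sum(vapply(x, function(m) nrow(m@pairs), 1L))
  nMiss <- sum(vapply(x, function(m) m@nMiss, 1L))
  nFalse <- sum(vapply(x, function(m) m@nFalse, 1L))
  nTrue <- nMatch + nMiss
  nEst <- nMatch + nFalse
  if (nTrue == 0 && nEst == 0) {
    out <- c(sensitivity = 1, precision = 1, er = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  sens <- if (nTrue > 0) nMatch / nTrue else 0
  prec <- if (nEst > 0) nMatch / nEst else 0
  er <- if (sens + prec > 0) 1 - 2 * sens * prec / (sens + prec) else 1
  c(sensitivity = sens, precision = prec, er = er)
}

#' @rdname errorStats
#' @param x a [MatchResult-class].
#' @export
setMethod("errorRate", "MatchResult", function(x)
  unname(errorStats(x)["er"]))

#' Mean temporal error of a matching
#'
#' Average absolute delay between matched estimated and true spikes.
#'
#' @param match a [MatchResult-class] or a list of them (pooled pairs).
#' @return mean |delay| in seconds; \code{NA} (with a warning) when there
#'   are no matched pairs.
#' @export
meanTemporalError <- function(match) {
  if (is(match, "MatchResult")) match <- list(match)
  d <- unlist(lapply(match, function(m)
    if (nrow(m@pairs)) abs(m@pairs[, 1] - m@pairs[, 2]) else numeric(0)))
  if (!length(d)) {
    warning("no matched pairs; temporal error undefined")
    return(NA_real_)
  }
  mean(d)
}

#' Correlation between true spike counts and an estimated rate
#'
#' Bins the reference spikes (default 40 ms bins) and correlates them with
#' the estimated instantaneous rate.  A spike-train estimate is binned
#' likewise and smoothed with a Gaussian kernel (default SD 100 ms); the
#' same kernel is then applied to the reference counts so that a perfect
#' spike-train estimate yields a correlation of exactly 1.  A numeric rate
#' series is interpolated onto the bin centers and compared against the
#' raw binned counts (the convention used to compare against algorithms
#' that return rates rather than spikes).
#'
#' @param true reference spike train.
#' @param est estimated [SpikeTrain-class], or numeric rate series (one
#'   value per frame) with frame interval \code{estDt}.
#' @param bin bin width (s) for the true counts.
#' @param kernel Gaussian smoothing SD (s) applied to spike-train estimates.
#' @param duration common duration (s); default covers both inputs.
#' @param estDt frame interval of a numeric \code{est} series.
#' @return Pearson correlation; \code{NA} with a warning when either vector
#'   has zero variance.
#' @export
rateCorrelation <- function(true, est, bin = 0.04, kernel = 0.1,
                            duration = NULL, estDt = NULL) {
  st <- spikeTimes(true)
  if (is.null(duration)) {
    dmax <- if (length(st)) max(st) else 0
    if (is(est, "SpikeTrain") || is(est, "MapResult")) {
      se <- spikeTimes(est)
      if (length(se)) dmax <- max(dmax, max(se))
    } else if (!is.null(estDt)) dmax <- max(dmax, length(est) * estDt)
    duration <- dmax + bin
  }
  nb <- max(2L, as.integer(ceiling(duration / bin)))
  edges <- (0:nb) * bin
  ctrue <- graphics::hist(st[st < nb * bin], breaks = edges,
                          plot = FALSE)$counts
  if (is(est, "SpikeTrain") || is(est, "MapResult")) {
    se <- spikeTimes(est)
    cest <- graphics::hist(se[se < nb * bin], breaks = edges,
                           plot = FALSE)$counts
    cest <- gaussSmooth(cest, kernel / bin)
    ctrue <- gaussSmooth(ctrue, kernel / bin)
  } else {
    if (is.null(estDt)) stop("numeric 'est' requires 'estDt'")
    centers <- (seq_len(nb) - 0.5) * bin
    cest <- stats::approx((seq_along(est) - 0.5) * estDt, est,
                          xout = centers, rule = 2)$y
  }
  if (stats::sd(ctrue) == 0 || stats::sd(cest) == 0) {
    warning("zero-variance rate vector; correlation undefined")
    return(NA_real_)
  }
  stats::cor(ctrue, cest)
}

## internal: Gaussian kernel smoothing, SD in samples, edge-renormalized
gaussSmooth <- function(x, sdSamples) {
  if (sdSamples <= 0) return(x)
  half <- max(1L, ceiling(4 * sdSamples))
  k <- stats::dnorm(seq(-half, half), sd = sdSamples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(numeric(half), x, numeric(half))
  y <- stats::filter(xp, k, sides = 2)[(half + 1):(half + n)]
  norm <- stats::filter(c(numeric(half), rep(1, n), numeric(half)), k,
                        sides = 2)[(half + 1):(half + n)]
  as.numeric(y / norm)
}

#' Residual noise level of a trace
#'
#' RMS of the difference between the measured trace and the model-predicted
#' noiseless trace, restricted to the 0.1--3 Hz band, normalized by the
#' effective unitary amplitude \eqn{A'} (see [computeAPrime()]).
#'
#' @param trace a [FluoTrace-class] or numeric vector.
#' @param predicted noiseless predicted trace (same length).
#' @param APrime effective per-spike amplitude (\eqn{> 0}).
#' @param band measurement band (Hz).
#' @param dt frame interval (s); taken from \code{trace} when it is a
#'   [FluoTrace-class].
#' @return dimensionless noise level.
#' @export
noiseLevel <- function(trace, predicted, APrime, band = c(0.1, 3),
                       dt = NULL) {
  if (is(trace, "FluoTrace")) {
    dt <- trace@dt
    trace <- trace@values
  }
  if (is.null(dt)) stop("'dt' required for a numeric trace")
  stopifnot(length(trace) == length(predicted))
  if (APrime <= 0) stop("'APrime' must be > 0")
  bandRMS(trace - predicted, dt, band) / APrime
}

#' Effective per-spike amplitude A'
#'
#' The "average response to one spike" used to normalize noise levels: half
#' of the response to two spikes, \eqn{A' = A\,g(2)/2}, or 1/15 of the
#' response to 15 spikes for the GCaMP5k profile.  \eqn{A' \le A} for
#' saturating probes and \eqn{A' \ge A} for supra-linear ones.
#'
#' @param params a [ModelParams-class].
#' @param nRef number of reference spikes; defaults to 15 when the
#'   parameters carry the \code{gcamp5k} profile attribute, else 2.
#' @return \eqn{A'} in \eqn{\Delta F/F} units.
#' @examples
#' computeAPrime(modelParams(A = 0.1, probe = "saturating", gamma = 0.1))
#' @export
computeAPrime <- function(params, nRef = NULL) {
  if (is.null(nRef))
    nRef <- if (identical(attr(params, "profile"), "gcamp5k")) 15 else 2
  params@A * probeResponse(nRef, params) / nRef
}

#' Photomultiplier photonic-gain calibration
#'
#' For a signal whose fast fluctuations are purely photonic (shot) noise,
#' the noise variance is gain times the mean signal.  System noise
#' dominates at low frequencies, so the signal (e.g. from a fluorescent
#' bead imaged at high rate \eqn{f_s}) is high-pass filtered above
#' \eqn{f_c}; since shot noise has a flat spectrum on \eqn{[0, f_s/2]},
#' the full photonic variance is recovered as the high-passed variance
#' times \eqn{(f_s/2)/((f_s/2) - f_c)}, and the gain is that variance
#' divided by the mean signal.
#'
#' @param bead numeric bead signal (arbitrary photon-count-proportional
#'   units).
#' @param fs sampling rate (Hz), must exceed \eqn{2 f_c}.
#' @param fc high-pass cutoff (Hz), default 200.
#' @return estimated gain (signal units per photon).
#' @export
photonicGain <- function(bead, fs, fc = 200) {
  stopifnot(fs > 2 * fc)
  mu <- mean(bead)
  if (mu <= 0) stop("signal mean must be positive")
  if (stats::var(bead) == 0) return(0)
  hp <- bead - fftLowpass(bead, 1 / fs, fc)
  v <- mean((hp - mean(hp))^2)
  v * ((fs / 2) / (fs / 2 - fc)) / mu
}

#' Photonic contribution to the band-limited noise RMS
#'
#' Given a calibrated gain, the photonic noise RMS of a new signal of mean
#' \eqn{\mu} acquired at frame rate \eqn{f}, inside a band
#' \eqn{[f_1, f_2]}, is \eqn{\sqrt{\hat a \mu \cdot 2(f_2-f_1)/f}} (flat
#' shot-noise spectrum).
#'
#' @param gain calibrated photonic gain (see [photonicGain()]).
#' @param meanSignal mean of the new signal.
#' @param f frame rate of the new signal (Hz).
#' @param band frequency band (Hz).
#' @return photonic band RMS in signal units.
#' @export
photonicBandRMS <- function(gain, meanSignal, f, band = c(0.1, 3)) {
  stopifnot(gain >= 0, meanSignal >= 0)
  sqrt(gain * meanSignal * 2 * (band[2] - band[1]) / f)
}

#' Evaluate an estimated spike train against a reference
#'
#' Convenience wrapper combining [matchSpikes()], [errorStats()],
#' [meanTemporalError()] and [rateCorrelation()] into an
#' [EvalReport-class].
#'
#' @param true reference spike train.
#' @param est estimated spike train.
#' @param tolerance matching tolerance (s).
#' @param bin,kernel see [rateCorrelation()].
#' @param duration common duration (s).
#' @return an [EvalReport-class].
#' @export
evalSpikes <- function(true, est, tolerance = 0.5, bin = 0.04,
                       kernel = 0.1, duration = NULL) {
  m <- matchSpikes(true, est, tolerance)
  st <- errorStats(m)
  mte <- if (nrow(m@pairs)) meanTemporalError(m) else NA_real_
  r <- suppressWarnings(
    rateCorrelation(true, if (is(est, "MapResult")) est@spikes else
      spikeTrain(spikeTimes(est)), bin = bin, kernel = kernel,
      duration = duration))
  new("EvalReport", sensitivity = unname(st["sensitivity"]),
      precision = unname(st["precision"]), er = unname(st["er"]),
      meanTemporalError = mte, correlation = r,
      counts = c(nTrue = nrow(m@pairs) + m@nMiss,
                 nEst = nrow(m@pairs) + m@nFalse,
                 nMatch = nrow(m@pairs)))
}
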