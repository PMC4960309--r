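#' @include AllClasses.R AllGenerics.R
NULL

#' Create a set of model parameters
#'
#' @param A unitary transient amplitude (\eqn{\Delta F/F} per spike).
#' @param tau calcium decay time constant (s).
#' @param probe probe nonlinearity type; see [ModelParams-class].
#' @param gamma saturation parameter (saturating/hill probes).
#' @param p2,p3 cubic polynomial coefficients (polynomial probe).
#' @param nHill Hill exponent (hill probes).
#' @param c0 normalized resting calcium.
#' @param tauOn probe binding time constant (s; hill_rise probe).
#' @param delay fixed spike-to-onset delay (s).
#' @param sigma measurement noise SD per sample.
#' @param eta baseline drift amplitude (\eqn{\Delta F/F\,s^{-1/2}}).
#' @param lam a priori spike rate (spikes/s).
#' @param nmax maximum spikes per time bin.
#' @return a validated [ModelParams-class] object.
#' @examples
#' p <- modelParams(A = 0.1, tau = 1, probe = "saturating", gamma = 0.1)
#' @export
modelParams <- function(A = 0.1, tau = 1, probe = "linear", gamma = 0.1,
                        p2 = 0.73, p3 = -0.05, nHill = 2, c0 = 0,
                        tauOn = 0, delay = 0, sigma = 0.02, eta = 0,
                        lam = 0.1, nmax = 3L) {
  new("ModelParams", A = A, tau = tau, probe = probe, gamma = gamma,
      p2 = p2, p3 = p3, nHill = nHill, c0 = c0, tauOn = tauOn,
      delay = delay, sigma = sigma, eta = eta, lam = lam,
      nmax = as.integer(nmax))
}

#' Standard probe profiles
#'
#' Returns model parameters preset for a calcium indicator, using the field's
#' average calibrated values: OGB is modelled as a saturating dye with
#' \eqn{\gamma = 0.1}; GCaMP6s and GCaMP6f as cubic polynomials with
#' coefficients [0.73, -0.05] and [0.55, 0.03] and fixed onset delays of 20
#' and 10 ms respectively.  The profile also carries the autocalibration
#' settings (amplitude search range and the noise-underestimation bias).
#'
#' @param name one of \code{"ogb"}, \code{"gcamp6s"}, \code{"gcamp6f"},
#'   \code{"gcamp5k"}.
#' @param ... overrides passed on to [modelParams()].
#' @return a [ModelParams-class] with attributes \code{profile},
#'   \code{Amin}, \code{Amax} (autocalibration amplitude bounds) and
#'   \code{sigmaBias} (multiplicative bias on the noise estimate).
#' @examples
#' probeProfile("ogb")
#' @export
probeProfile <- function(name = c("ogb", "gcamp6s", "gcamp6f", "gcamp5k"),
                         ...) {
  name <- match.arg(name)
  args <- switch(name,
    ogb     = list(A = 0.052, tau = 0.81, probe = "saturating", gamma = 0.1),
    gcamp6s = list(A = 0.1, tau = 1, probe = "polynomial",
                   p2 = 0.73, p3 = -0.05, delay = 0.02),
    gcamp6f = list(A = 0.05, tau = 0.5, probe = "polynomial",
                   p2 = 0.55, p3 = 0.03, delay = 0.01),
    gcamp5k = list(A = 0.05, tau = 1, probe = "polynomial",
                   p2 = 0.73, p3 = -0.05))
  over <- list(...)
  args[names(over)] <- over
  p <- do.call(modelParams, args)
  attr(p, "profile") <- name
  attr(p, "Amin") <- 0.04
  attr(p, "Amax") <- 0.10
  # noise bias applied for OGB and GCaMP6f; GCaMP6s/5k unbiased
  attr(p, "sigmaBias") <- if (name %in% c("ogb", "gcamp6f")) 0.7 else 1
  p
}

#' Create a spike train
#'
#' @param times spike times (s); sorted internally.
#' @param counts optional per-bin counts (integer per frame).
#' @param dt bin width (s), required with \code{counts}.
#' @return a [SpikeTrain-class].  When built from \code{counts}, spike times
#'   are placed at bin midpoints: a count in frame \eqn{k} (frames at
#'   \eqn{(k-1)dt}) represents spikes in \eqn{((k-2)dt, (k-1)dt]} and is
#'   reported at \eqn{(k-1.5)dt}.
#' @examples
#' spikeTrain(c(0.5, 1.2, 3.0))
#' @export
spikeTrain <- function(times = numeric(0), counts = NULL, dt = NULL) {
  if (!is.null(counts)) {
    stopifnot(!is.null(dt))
    counts <- as.integer(round(counts))
    k <- rep.int(seq_along(counts), counts)
    times <- (k - 1.5) * dt
    times[times < 0] <- 0
    new("SpikeTrain", times = times, counts = counts, dt = dt)
  } else {
    new("SpikeTrain", times = sort(as.numeric(times)))
  }
}

#' Create a fluorescence trace
#'
#' @param values per-frame fluorescence (relative units).
#' @param dt frame interval (s); exactly one of \code{dt} and \code{rate}.
#' @param rate frame rate (Hz).
#' @return a [FluoTrace-class].
#' @examples
#' fluoTrace(rnorm(100, 1, 0.01), rate = 100)
#' @export
fluoTrace <- function(values, dt = NULL, rate = NULL) {
  if (is.null(dt) == is.null(rate))
    stop("supply exactly one of 'dt' and 'rate'")
  if (is.null(dt)) dt <- 1 / rate
  new("FluoTrace", values = as.numeric(values), dt = dt)
}

#' Create a noise specification
#'
#' @param kind noise regime: \code{"white"}, \code{"white_plus_drift"} or
#'   \code{"pink"}.
#' @param level band-RMS noise level in units of A (see [bandRMS()]).
#' @param band measurement band (Hz).
#' @return a [NoiseSpec-class].
#' @examples
#' noiseSpec("pink", level = 0.2)
#' @export
noiseSpec <- function(kind = c("white", "white_plus_drift", "pink"),
                      level = 0.1, band = c(0.1, 3)) {
  new("NoiseSpec", kind = match.arg(kind), level = level, band = band)
}

## ---- accessors ----

#' @rdname spikeTimes
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x, ...) x@times)

#' @rdname spikeTimes
#' @export
setMethod("spikeTimes", "MapResult", function(x, ...) x@spikes@times)

#' @rdname spikeTimes
#' @export
setMethod("spikeTimes", "numeric", function(x, ...) sort(as.numeric(x)))

#' @rdname nSpikes
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

#' @rdname nSpikes
#' @export
setMethod("nSpikes", "MapResult", function(x) length(x@spikes@times))

#' @rdname spikeCounts
#' @export
setMethod("spikeCounts", "SpikeTrain", function(x, dt = NULL, duration = NULL) {
  if (is.null(dt)) {
    if (length(x@counts)) return(x@counts)
    stop("no stored counts; supply 'dt'")
  }
  binSpikeTimes(x@times, dt, duration)
})

#' @rdname spikeCounts
#' @export
setMethod("spikeCounts", "MapResult", function(x, dt = NULL, duration = NULL)
  x@spikes@counts)

#' @rdname traceValues
#' @export
setMethod("traceValues", "FluoTrace", function(x) x@values)

#' @rdname traceValues
#' @export
setMethod("traceValues", "MapResult", function(x) x@fit)

#' @rdname frameDt
#' @export
setMethod("frameDt", "FluoTrace", function(x) x@dt)

#' @rdname frameDt
#' @export
setMethod("frameDt", "MapResult", function(x) x@dt)

#' @rdname frameDt
#' @export
setMethod("frameDt", "SpikePosterior", function(x) x@dt)

#' @rdname duration
#' @export
setMethod("duration", "FluoTrace", function(x) length(x@values) * x@dt)

#' @rdname duration
#' @export
setMethod("duration", "SpikeTrain", function(x) {
  if (length(x@counts)) length(x@counts) * x@dt
  else if (length(x@times)) max(x@times) else 0
})

#' @rdname latentPath
#' @export
setMethod("latentPath", "MapResult", function(x) x@path)

#' @rdname logPosterior
#' @export
setMethod("logPosterior", "MapResult", function(x) x@logPosterior)

#' @rdname spikeMarginals
#' @export
setMethod("spikeMarginals", "SpikePosterior", function(x) x@spikeMarginals)

#' @rdname errorRate
#' @export
setMethod("errorRate", "EvalReport", function(x) x@er)

## ---- show methods ----

setMethod("show", "ModelParams", function(object) {
  cat(sprintf("ModelParams: probe=%s A=%.3g tau=%.3gs sigma=%.3g eta=%.3g lambda=%.3g nmax=%d\n",
              object@probe, object@A, object@tau, object@sigma, object@eta,
              object@lam, object@nmax))
  extra <- switch(object@probe,
    saturating = sprintf("  gamma=%.3g", object@gamma),
    polynomial = sprintf("  p2=%.3g p3=%.3g", object@p2, object@p3),
    hill = sprintf("  gamma=%.3g nHill=%.3g c0=%.3g", object@gamma,
                   object@nHill, object@c0),
    hill_rise = sprintf("  gamma=%.3g nHill=%.3g c0=%.3g tauOn=%.3gs",
                        object@gamma, object@nHill, object@c0, object@tauOn),
    NULL)
  if (!is.null(extra)) cat(extra, "\n")
  if (object@delay > 0) cat(sprintf("  onset delay=%.3gs\n", object@delay))
})

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes", length(object@times)))
  if (length(object@times))
    cat(sprintf(" in [%.3g, %.3g] s", min(object@times), max(object@times)))
  cat("\n")
})

setMethod("show", "FluoTrace", function(object) {
  cat(sprintf("FluoTrace: %d frames at %.4g Hz (%.3g s)\n",
              length(object@values), 1 / object@dt,
              length(object@values) * object@dt))
})

setMethod("show", "MapResult", function(object) {
  cat(sprintf("MapResult: %d spikes, log posterior %.4f\n",
              length(object@spikes@times), object@logPosterior))
})

setMethod("show", "SpikePosterior", function(object) {
  cat(sprintf("SpikePosterior: %d bins, expected total %.3g spikes, log evidence %.4f\n",
              nrow(object@spikeMarginals), sum(object@expected),
              object@logEvidence))
})

setMethod("show", "CalibrationResult", function(object) {
  cat(sprintf("CalibrationResult: A=%.3g%% tau=%.3g s sigma=%s%s\n",
              100 * object@AHat, object@tauHat,
              paste(signif(object@sigmaHat, 3), collapse = "/"),
              if (object@fallback) " [fallback to profile defaults]" else ""))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: %d matched, %d missed, %d false (tol %.3g s)\n",
              nrow(object@pairs), object@nMiss, object@nFalse,
              object@tolerance))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: ER=%.2f%% sens=%.3f prec=%.3f",
              100 * object@er, object@sensitivity, object@precision))
  if (!is.na(object@meanTemporalError))
    cat(sprintf(" <|dt|>=%.1f ms", 1000 * object@meanTemporalError))
  if (!is.na(object@correlation)) cat(sprintf(" r=%.3f", object@correlation))
  cat("\n")
})

## internal: bin spike times onto frames (frame k at time (k-1)*dt carries
## spikes in ((k-2)*dt, (k-1)*dt]); a spike at exactly t=0 lands in frame 2's
## bin so that it takes effect at the first frame at or after it.
binSpikeTimes <- function(times, dt, duration = NULL) {
  if (is.null(duration)) duration <- if (length(times)) max(times) + dt else dt
  nT <- max(2L, as.integer(ceiling(duration / dt)))
  k <- pmin(pmax(ceiling(times / dt - 1e-12) + 1L, 2L), nT)
  counts <- integer(nT)
  if (length(k)) {
    tb <- tabulate(k, nbins = nT)
    counts <- as.integer(tb)
  }
  counts
}
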