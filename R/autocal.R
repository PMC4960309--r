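#' @include infer.R metrics.R
NULL

## cache for the Monte-Carlo corrective factors of estimateSigma
.sigmaCache <- new.env(parent = emptyenv())

#' Estimate the measurement noise SD from a trace
#'
#' The noise SD \eqn{\sigma} is estimated as the RMS of the trace band-pass
#' filtered between 3 and 20 Hz -- a band where calcium-related signal
#' contributes little -- multiplied by a corrective factor chosen so that
#' pure white noise returns its true standard deviation.  The factor is
#' determined once per (frame rate, band) by a large white-noise
#' Monte-Carlo run and cached.  For the OGB and GCaMP6f probe profiles the
#' result is multiplied by an additional bias of 0.7, deliberately
#' underestimating the noise to balance misses against false detections.
#'
#' @param trace a [FluoTrace-class] or numeric vector.
#' @param profile optional [probeProfile()] parameters; supplies the bias.
#' @param band filter band (Hz), default \code{c(3, 20)}; clipped (with a
#'   warning) when the frame rate is below 40 Hz.
#' @param bias multiplicative bias; overrides the profile's
#'   (\code{0.7} for OGB/GCaMP6f, 1 otherwise).
#' @param dt frame interval for numeric traces.
#' @return estimated noise SD (\eqn{\Delta F/F} per sample).
#' @examples
#' x <- fluoTrace(rnorm(4000, 1, 0.02), rate = 100)
#' estimateSigma(x)   # about 0.02
#' @export
estimateSigma <- function(trace, profile = NULL, band = c(3, 20),
                          bias = NULL, dt = NULL) {
  if (is(trace, "FluoTrace")) { x <- trace@values; dt <- trace@dt }
  else { x <- as.numeric(trace); stopifnot(!is.null(dt)) }
  if (length(x) < 64) stop("trace too short to estimate sigma")
  nyq <- 1 / (2 * dt)
  if (band[2] > nyq) {
    warning("frame rate too low for the 3-20 Hz band; clipping at Nyquist")
    band[2] <- nyq * 0.999
  }
  if (band[1] >= band[2]) stop("degenerate filter band")
  if (is.null(bias)) {
    bias <- if (!is.null(profile) && !is.null(attr(profile, "sigmaBias")))
      attr(profile, "sigmaBias") else 1
  }
  key <- sprintf("%.6g_%.4g_%.4g", dt, band[1], band[2])
  if (is.null(.sigmaCache[[key]])) {
    n <- 2^20
    w <- withr::with_seed(20240101L, stats::rnorm(n))
    r <- sqrt(mean(fftBandpass(w, dt, band[1], band[2])^2))
    .sigmaCache[[key]] <- 1 / r
  }
  rms <- sqrt(mean(fftBandpass(x, dt, band[1], band[2])^2))
  rms * .sigmaCache[[key]] * bias
}

#' Default working parameters for calcium-event detection
#'
#' The event-detection stage of autocalibration runs the MAP engine with
#' standard working values (A = 10\%, tau = 0.8 s, event rate lambda = 0.1/s,
#' a small fixed baseline drift) and a linear response, since event
#' amplitudes are continuous and large transients are excluded later.
#'
#' @param sigma working noise SD (from [estimateSigma()]).
#' @param eta baseline drift amplitude; the optimal value varies little
#'   across cells and is fixed (default 0.02).
#' @return a [ModelParams-class].
#' @export
workingParams <- function(sigma, eta = 0.02) {
  modelParams(A = 0.10, tau = 0.8, probe = "linear", sigma = sigma,
              eta = eta, lam = 0.1)
}

#' Detect calcium events of arbitrary amplitude
#'
#' Runs the MAP engine with the per-bin spike-count maximization replaced
#' by a maximization over a continuous event amplitude (discretized on a
#' log-spaced candidate ladder, minimum \code{Amin}): the estimated input
#' is no longer a unitary spike train but a set of calcium events of
#' arbitrary amplitude.
#'
#' @param trace a [FluoTrace-class].
#' @param params working [ModelParams-class] (see [workingParams()]);
#'   \code{sigma} must be set.
#' @param control engine control; detection defaults to a coarser grid
#'   (50 x 50) since events are large, and to a calcium range just covering
#'   the largest candidate amplitude (cmax = 6 working-amplitude units for
#'   Amax = 50\%) -- a larger range only opens degenerate low-baseline /
#'   high-calcium explanations of the trace.
#' @param Amin minimal event amplitude (\eqn{\Delta F/F}), default 4\%.
#' @param Amax largest candidate amplitude (default 50\%, so that large
#'   transients are detected and can then be excluded).
#' @param nCandidates number of amplitude candidates.
#' @return data.frame with columns \code{time}, \code{amplitude},
#'   \code{bin}.
#' @export
detectEvents <- function(trace, params,
                         control = spikeControl(nc = 50, nb = 50, cmax = 6),
                         Amin = 0.04, Amax = 0.5, nCandidates = 12) {
  amps <- exp(seq(log(Amin), log(Amax), length.out = nCandidates))
  jumps <- c(0, amps / params@A)
  dt <- trace@dt
  logJump <- c(stats::dpois(0, params@lam * dt, log = TRUE),
               rep(stats::dpois(1, params@lam * dt, log = TRUE),
                   nCandidates))
  fc <- runViterbi(trace, params, control, jumps = jumps,
                   logJump = logJump, refineJump = TRUE)
  bins <- which(fc$jumps > 0)
  data.frame(time = (bins - 1) * dt,
             amplitude = fc$jumps[bins] * params@A,
             bin = bins)
}

#' Select isolated events and re-fit their amplitudes
#'
#' Single-spike amplitudes are best estimated from isolated transients of
#' moderate size: events closer than 1 s to another event, or larger than
#' 25\% \eqn{\Delta F/F}, are excluded.  The predicted transients of the
#' excluded events are subtracted from the trace, and the amplitudes of the
#' kept events together with a shared decay time constant are re-estimated
#' by least squares on the cleaned signals.
#'
#' @param events data.frame from [detectEvents()] with an added
#'   \code{trial} column (added automatically for a single trace).
#' @param traces a [FluoTrace-class] or list of them (one per trial).
#' @param params working [ModelParams-class] (supplies the initial tau).
#' Detected jumps closer than \code{mergeWindow} (default 50 ms) are first
#' merged into a single calcium event with their amplitudes summed: a
#' spike burst (about 10 ms inter-spike intervals) raises calcium across
#' adjacent frames but constitutes one transient, and it is these summed
#' amplitudes that populate the 2-, 3-, ... spike peaks of the amplitude
#' histogram.
#'
#' @param minSeparation exclusion distance (s).
#' @param maxAmplitude exclusion amplitude (\eqn{\Delta F/F}).
#' @param mergeWindow events closer than this (s) are one transient.
#' @param Amin minimal credible event amplitude: kept events whose
#'   re-fitted amplitude drops below \code{Amin/2} are detection residue
#'   (e.g. tail patches from a mismatched working decay) and are removed,
#'   with one final re-fit.
#' @param tauRange search bounds for the shared decay constant (s).
#' @return list with \code{events} (kept, amplitudes re-fitted),
#'   \code{tau} (shared re-fitted decay), \code{cleaned} (list of cleaned
#'   value vectors), or \code{NULL} when no event survives.
#' @export
selectIsolatedEvents <- function(events, traces, params,
                                 minSeparation = 1, maxAmplitude = 0.25,
                                 Amin = 0.04, tauRange = c(0.1, 3),
                                 mergeWindow = 0.05) {
  if (is(traces, "FluoTrace")) traces <- list(traces)
  if (is.null(events$trial)) events$trial <- 1L
  if (!nrow(events)) return(NULL)
  ## merge near-coincident jumps (one burst = one transient)
  events <- do.call(rbind, lapply(split(events, events$trial), function(ev) {
    ev <- ev[order(ev$time), , drop = FALSE]
    grp <- cumsum(c(1, diff(ev$time) > mergeWindow))
    data.frame(time = tapply(ev$time, grp, min),
               amplitude = as.numeric(tapply(ev$amplitude, grp, sum)),
               bin = as.integer(tapply(ev$bin, grp, min)),
               trial = ev$trial[1])
  }))
  rownames(events) <- NULL
  keep <- logical(nrow(events))
  for (tr in unique(events$trial)) {
    i <- which(events$trial == tr)
    tt <- events$time[i]
    sep <- if (length(tt) == 1) rep(Inf, 1)
           else pmin(c(Inf, diff(tt)), c(diff(tt), Inf))
    keep[i] <- sep >= minSeparation & events$amplitude[i] <= maxAmplitude
  }
  excluded <- events[!keep, , drop = FALSE]
  kept <- events[keep, , drop = FALSE]
  if (!nrow(kept)) return(NULL)
  b0s <- vapply(traces, function(tr)
    as.numeric(stats::quantile(tr@values, 0.10)), 0)
  ## trace with the excluded events' predicted transients removed; the
  ## subtraction must use the same decay constant as the fit, otherwise
  ## mismatched tails bias the kept-event estimation
  cleanFor <- function(tr, tau) {
    y <- traces[[tr]]@values
    dt <- traces[[tr]]@dt
    ex <- excluded[excluded$trial == tr, , drop = FALSE]
    if (nrow(ex)) {
      tgrid <- (seq_along(y) - 1) * dt
      for (e in seq_len(nrow(ex))) {
        d <- tgrid - ex$time[e]
        y <- y - b0s[tr] * ex$amplitude[e] * ifelse(d >= 0, exp(-d / tau), 0)
      }
    }
    y
  }
  ## re-estimate amplitudes (per event) and a shared tau by least squares
  fitFor <- function(tau) {
    rss <- 0
    amps <- numeric(nrow(kept))
    for (tr in unique(kept$trial)) {
      i <- which(kept$trial == tr)
      y <- cleanFor(tr, tau)
      dt <- traces[[tr]]@dt
      tgrid <- (seq_along(y) - 1) * dt
      X <- vapply(kept$time[i], function(t0) {
        d <- tgrid - t0
        b0s[tr] * ifelse(d >= 0, exp(-d / tau), 0)
      }, numeric(length(y)))
      fit <- stats::lm.fit(cbind(1, X), y)
      amps[i] <- fit$coefficients[-1]
      rss <- rss + sum(fit$residuals^2)
    }
    list(rss = rss, amps = amps)
  }
  repeat {
    tau <- stats::optimize(function(tau) fitFor(tau)$rss,
                           interval = tauRange)$minimum
    refit <- fitFor(tau)
    kept$amplitude <- refit$amps
    ok <- is.finite(kept$amplitude) & kept$amplitude >= Amin / 2
    if (all(ok) || !any(ok)) break
    kept <- kept[ok, , drop = FALSE]
  }
  kept <- kept[is.finite(kept$amplitude) & kept$amplitude >= Amin / 2, ,
               drop = FALSE]
  if (!nrow(kept)) return(NULL)
  list(events = kept, tau = tau,
       cleaned = lapply(seq_along(traces), cleanFor, tau = tau))
}

#' Amplitude of a multi-spike transient
#'
#' The peak \eqn{\Delta F/F} response to \code{k} simultaneous spikes under
#' the probe nonlinearity: \eqn{A\,g(k)}.  Linear probes give exactly
#' \eqn{kA}; saturating probes less, supra-linear probes more.
#'
#' @param A unitary amplitude.
#' @param k number of spikes.
#' @param params a [ModelParams-class] (supplies the nonlinearity).
#' @return amplitude in \eqn{\Delta F/F}.
#' @export
multiSpikeAmplitude <- function(A, k, params) A * probeResponse(k, params)

#' Estimate the unitary amplitude from an event-amplitude histogram
#'
#' Exploits the discreteness of spikes: transient amplitudes cluster at the
#' 1-, 2-, ... spike responses.  A histogram of event amplitudes is
#' smoothed (x1), peaks are enhanced by dividing x1 by a low-passed version
#' of itself (x2), and a cost function \eqn{x_3(A) = x_2(A) +
#' x_2(a_2(A))/2} is maximized over a bounded range, where \eqn{a_2(A)} is
#' the two-spike amplitude under the probe nonlinearity (\eqn{2A} for a
#' linear probe).
#'
#' @param amplitudes event amplitudes (\eqn{\Delta F/F}), at least 3.
#' @param params a [ModelParams-class] for the nonlinearity.
#' @param bounds search range \code{c(Amin, Amax)}, default 4--10\%.
#' @param nBins histogram bins (over \code{[0, 1.2 max(amplitudes)]}).
#' @param smoothSd x1 Gaussian kernel SD, in bins.
#' @param lowpassSd x2 low-pass Gaussian SD, in bins.
#' @return the estimated amplitude, with the diagnostic curves attached as
#'   attribute \code{diagnostics} (bin centers, x1, x2, A grid, x3).
#' @export
histogramCostA <- function(amplitudes, params, bounds = c(0.04, 0.10),
                           nBins = 40, smoothSd = 1, lowpassSd = 8) {
  if (!length(amplitudes)) stop("empty amplitude list")
  if (length(amplitudes) < 3) stop("need at least 3 event amplitudes")
  hi <- 1.2 * max(amplitudes)
  edges <- seq(0, hi, length.out = nBins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  counts <- graphics::hist(pmin(amplitudes, hi), breaks = edges,
                           plot = FALSE)$counts
  x1 <- gaussSmooth(counts, smoothSd)
  lp <- gaussSmooth(x1, lowpassSd)
  x2 <- x1 / pmax(lp, max(lp) * 1e-6)
  x2f <- stats::approxfun(centers, x2, rule = 2)
  Agrid <- seq(bounds[1], bounds[2], length.out = 241)
  amp2 <- multiSpikeAmplitude(Agrid, 2, params)
  x3 <- x2f(Agrid) + x2f(amp2) / 2
  AHat <- Agrid[which.max(x3)]
  attr(AHat, "diagnostics") <- list(centers = centers, x1 = x1, x2 = x2,
                                    Agrid = Agrid, x3 = x3)
  AHat
}

#' Assign spike counts to event amplitudes
#'
#' Events are assigned \code{k} spikes when their amplitude falls between
#' the separations at \eqn{(k-1+0.3)A} and \eqn{(k+0.3)A}, generalized to
#' nonlinear probes by placing the separation between \code{k} and
#' \code{k+1} spikes 30\% of the way from the k-spike to the (k+1)-spike
#' amplitude.  Amplitudes at or below \eqn{0.3A} get zero spikes (the event
#' is dropped downstream).
#'
#' @param amplitudes event amplitudes (\eqn{\Delta F/F}).
#' @param AHat estimated unitary amplitude.
#' @param params a [ModelParams-class] for the nonlinearity.
#' @param kMax largest count considered.
#' @return integer spike counts, same length as \code{amplitudes}.
#' @examples
#' p <- modelParams(probe = "linear")
#' assignSpikeCounts(c(0.05, 0.075, 0.01) , 0.05, p)  # 1, 2, 0
#' @export
assignSpikeCounts <- function(amplitudes, AHat, params, kMax = 20) {
  stopifnot(AHat > 0)
  gk <- multiSpikeAmplitude(AHat, 0:(kMax + 1), params)
  sep <- 0.7 * gk[1:(kMax + 1)] + 0.3 * gk[2:(kMax + 2)]  # between k and k+1
  vapply(amplitudes, function(a) sum(a > sep), 0L)
}

#' Final least-squares calibration of A and tau
#'
#' Given spike trains (event times with assigned counts), fits the forward
#' model to the cleaned traces over the amplitude and decay time constant,
#' with the probe nonlinearity fixed and a per-trial constant baseline
#' solved analytically.
#'
#' @param traces list of [FluoTrace-class] (or cleaned value vectors with
#'   \code{dts}).
#' @param spikeTimes list (per trial) of event times (s).
#' @param spikeCounts list (per trial) of integer counts per event.
#' @param params a [ModelParams-class] (nonlinearity).
#' @param init initial \code{c(A, tau)}.
#' @param dts frame intervals when traces are numeric vectors.
#' @return named vector \code{c(A, tau)}.
#' @export
calibrateATau <- function(traces, spikeTimes, spikeCounts, params,
                          init = c(0.07, 0.8), dts = NULL) {
  if (is(traces, "FluoTrace")) traces <- list(traces)
  vals <- lapply(traces, function(tr)
    if (is(tr, "FluoTrace")) tr@values else as.numeric(tr))
  if (is.null(dts))
    dts <- vapply(traces, function(tr)
      if (is(tr, "FluoTrace")) tr@dt else stop("'dts' required"), 0)
  if (length(dts) == 1) dts <- rep(dts, length(vals))
  nUsed <- sum(vapply(spikeCounts, function(k) sum(k > 0), 0))
  if (nUsed < 1) stop("no assigned spikes to calibrate on")
  rssFor <- function(logPar) {
    A <- exp(logPar[1]); tau <- exp(logPar[2])
    tot <- 0
    for (i in seq_along(vals)) {
      y <- vals[[i]]
      dt <- dts[i]
      counts <- numeric(length(y))
      if (length(spikeTimes[[i]])) {
        bins <- pmin(pmax(ceiling(spikeTimes[[i]] / dt - 1e-12) + 1L, 1L),
                     length(y))
        for (e in seq_along(bins))
          counts[bins[e]] <- counts[bins[e]] + spikeCounts[[i]][e]
      }
      decay <- exp(-dt / tau)
      cc <- numeric(length(y)); run <- 0
      for (t in seq_along(y)) { run <- run * decay + counts[t]; cc[t] <- run }
      u <- 1 + A * probeResponse(cc, params)
      b0 <- sum(y * u) / sum(u * u)
      tot <- tot + sum((y - b0 * u)^2)
    }
    tot
  }
  fit <- stats::optim(log(init), rssFor, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  if (fit$convergence != 0)
    stop("calibration optimizer failed to converge (code ",
         fit$convergence, ")")
  c(A = exp(fit$par[1]), tau = exp(fit$par[2]))
}

#' Least-squares single-exponential fit
#'
#' Fits \eqn{a\,e^{-t/\tau}} to data by unweighted least squares, profiling
#' the amplitude (linear given tau) and optimizing tau numerically.
#'
#' @param t time points (s).
#' @param y values.
#' @param interval search interval for tau (s).
#' @return named vector \code{c(amplitude, tau)}.  All-zero input returns
#'   amplitude 0 (tau NA); non-decaying data yields a boundary tau with a
#'   warning.
#' @examples
#' t <- seq(0, 5, by = 0.001)
#' fitSingleExponential(t, 3 * exp(-t / 0.5))
#' @export
fitSingleExponential <- function(t, y, interval = NULL) {
  stopifnot(length(t) == length(y), length(t) >= 3)
  if (all(y == 0)) return(c(amplitude = 0, tau = NA_real_))
  if (is.null(interval)) interval <- c(max(t) * 1e-4, max(t) * 10)
  ampFor <- function(tau) {
    e <- exp(-t / tau)
    sum(y * e) / sum(e * e)
  }
  rss <- function(tau) {
    e <- exp(-t / tau)
    a <- sum(y * e) / sum(e * e)
    sum((y - a * e)^2)
  }
  opt <- stats::optimize(rss, interval = interval, tol = 1e-10)
  tau <- opt$minimum
  width <- interval[2] - interval[1]
  if (min(tau - interval[1], interval[2] - tau) < 1e-3 * width) {
    warning("tau estimate at the search boundary; data may not be decaying")
  } else {
    # polish in shrinking brackets for near-machine-precision recovery
    tau <- stats::optimize(rss, interval = tau * c(0.999, 1.001),
                           tol = .Machine$double.eps^0.75)$minimum
    tau <- stats::optimize(rss, interval = tau * c(1 - 1e-6, 1 + 1e-6),
                           tol = .Machine$double.eps^0.75)$minimum
  }
  c(amplitude = ampFor(tau), tau = tau)
}

#' Per-neuron autocalibration of A, tau and sigma
#'
#' Estimates the three parameters that matter most, directly from the
#' fluorescence: \eqn{\sigma} per session from the 3--20 Hz band RMS
#' ([estimateSigma()]); then, pooling all trials, calcium events of
#' arbitrary amplitude are detected ([detectEvents()]), isolated moderate
#' events selected and re-fitted ([selectIsolatedEvents()]), the unitary
#' amplitude estimated from the amplitude histogram ([histogramCostA()]),
#' spike counts assigned ([assignSpikeCounts()]) and final values of
#' \eqn{A} and \eqn{\tau} obtained by least squares ([calibrateATau()]).
#' The remaining parameters stay fixed: \eqn{\lambda = 0.1}/s, a fixed
#' small drift \eqn{\eta}, and the profile's nonlinearity.
#'
#' @param traces a [FluoTrace-class] or list of them (trials pooled for A
#'   and tau; sigma estimated per trace).
#' @param profile a [probeProfile()] parameter set (supplies nonlinearity,
#'   amplitude bounds, sigma bias and fallback values).
#' @param control engine control for event detection.
#' @param eta fixed working drift amplitude.
#' @param sigma optional known noise SD(s), bypassing [estimateSigma()].
#' @return a [CalibrationResult-class].  When no usable events are found
#'   the profile's default A and tau are returned with
#'   \code{fallback = TRUE} and a warning.
#' @export
autocalibrate <- function(traces, profile = probeProfile("ogb"),
                          control = spikeControl(nc = 50, nb = 50,
                                                 cmax = 6),
                          eta = 0.02, sigma = NULL) {
  if (is(traces, "FluoTrace")) traces <- list(traces)
  sigmaHat <- if (!is.null(sigma)) rep(sigma, length.out = length(traces))
  else vapply(traces, estimateSigma, 0, profile = profile)
  bounds <- c(attr(profile, "Amin") %||% 0.04,
              attr(profile, "Amax") %||% 0.10)
  events <- do.call(rbind, lapply(seq_along(traces), function(i) {
    wp <- workingParams(sigma = max(sigmaHat[i], 1e-4), eta = eta)
    ev <- detectEvents(traces[[i]], wp, control, Amin = bounds[1])
    if (nrow(ev)) ev$trial <- i
    ev
  }))
  fallback <- function(msg) {
    warning("autocalibration fallback: ", msg)
    new("CalibrationResult", AHat = profile@A, tauHat = profile@tau,
        sigmaHat = sigmaHat, events = data.frame(),
        diagnostics = list(), fallback = TRUE)
  }
  if (is.null(events) || !nrow(events))
    return(fallback("no calcium events detected"))
  wp <- workingParams(sigma = max(mean(sigmaHat), 1e-4), eta = eta)
  sel <- selectIsolatedEvents(events, traces, wp, Amin = bounds[1])
  if (is.null(sel) || nrow(sel$events) < 3)
    return(fallback("too few isolated events"))
  AHat0 <- tryCatch(
    histogramCostA(sel$events$amplitude, profile, bounds = bounds),
    error = function(e) NULL)
  if (is.null(AHat0)) return(fallback("amplitude histogram failed"))
  counts <- assignSpikeCounts(sel$events$amplitude, as.numeric(AHat0),
                              profile)
  sel$events$nSpikes <- counts
  use <- counts > 0
  if (!any(use)) return(fallback("no events above the 0.3 A threshold"))
  byTrial <- lapply(seq_along(traces), function(i) {
    j <- which(sel$events$trial == i & use)
    list(times = sel$events$time[j], counts = counts[j])
  })
  final <- tryCatch(
    calibrateATau(lapply(sel$cleaned, identity),
                  lapply(byTrial, `[[`, "times"),
                  lapply(byTrial, `[[`, "counts"),
                  profile, init = c(as.numeric(AHat0), sel$tau),
                  dts = vapply(traces, function(tr) tr@dt, 0)),
    error = function(e) NULL)
  if (is.null(final)) return(fallback("final least-squares fit failed"))
  ## a priori parameter ranges: amplitude within the profile bounds,
  ## decay within the physiological search range
  final["A"] <- min(max(final["A"], bounds[1]), bounds[2])
  final["tau"] <- min(max(final["tau"], 0.1), 3)
  new("CalibrationResult", AHat = unname(final["A"]),
      tauHat = unname(final["tau"]), sigmaHat = sigmaHat,
      events = sel$events,
      diagnostics = c(attr(AHat0, "diagnostics"),
                      list(AHistogram = as.numeric(AHat0),
                           tauRefit = sel$tau)),
      fallback = FALSE)
}

#' Model parameters from an autocalibration result
#'
#' @param calib a [CalibrationResult-class].
#' @param profile the [probeProfile()] used for calibration.
#' @param session which session's sigma to use (default 1).
#' @return a [ModelParams-class] with A, tau and sigma set from the
#'   calibration and the remaining parameters from the profile.
#' @export
calibratedParams <- function(calib, profile, session = 1) {
  p <- profile
  p@A <- calib@AHat
  p@tau <- calib@tauHat
  p@sigma <- calib@sigmaHat[session]
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
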