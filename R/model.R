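#' @include methods.R
NULL

#' One-step calcium evolution
#'
#' Discrete update of the normalized calcium concentration over one frame:
#' exponential decay towards rest followed by the unit jumps of the spikes
#' counted in that frame, \eqn{c' = c\,e^{-dt/\tau} + n}.  Decay is applied
#' first so a single spike always produces a transient of amplitude exactly
#' one (in normalized units).
#'
#' @param c normalized calcium (vectorized).
#' @param n spike count in the bin (non-negative integer, vectorized).
#' @param dt frame interval (s).
#' @param tau decay time constant (s).
#' @return updated normalized calcium.
#' @examples
#' evolveCalcium(0, 1, 0.01, 1)       # 1
#' evolveCalcium(1, 0, 1, 1)          # exp(-1)
#' @export
evolveCalcium <- function(c, n, dt, tau) {
  stopifnot(dt > 0, tau > 0)
  if (any(n < 0) || any(n != round(n)))
    stop("'n' must be a non-negative integer")
  if (any(c < 0)) stop("'c' must be >= 0")
  c * exp(-dt / tau) + n
}

#' Normalized probe nonlinearity
#'
#' The dimensionless response function \eqn{g(c)} of the probe, normalized so
#' that \eqn{g(0)=0} and \eqn{g(1)=1}: the fluorescence response is
#' \eqn{A\,g(c)}, and one spike from rest always yields amplitude \eqn{A}.
#'
#' \itemize{
#' \item linear: \eqn{g(c)=c};
#' \item saturating: \eqn{g(c)=(1+\gamma)c/(1+\gamma c)} -- sub-linear dye
#'   saturation reaching half its asymptote \eqn{(1+\gamma)/\gamma} at
#'   \eqn{c = 1/\gamma} spikes;
#' \item polynomial: \eqn{g(c)=(1-p_2-p_3)c+p_2c^2+p_3c^3} -- phenomenological
#'   GECI supra-linearity;
#' \item hill / hill_rise: \eqn{g(c)=(h(c)-h(0))/(h(1)-h(0))} with
#'   \eqn{h(x)=(c_0+x)^n/((c_0+x)^n+(c_0+1/\gamma)^n)} -- cooperative binding
#'   with saturation.  With \eqn{n=1, c_0=0} this reduces identically to the
#'   saturating form.
#' }
#'
#' @param c normalized calcium (vectorized, \eqn{\ge 0}).
#' @param params a [ModelParams-class].
#' @return \eqn{g(c)}, dimensionless.
#' @examples
#' p <- modelParams(probe = "saturating", gamma = 0.1)
#' probeResponse(1, p)    # exactly 1
#' @export
probeResponse <- function(c, params) {
  if (any(c < 0)) stop("'c' must be >= 0")
  switch(params@probe,
    linear = c,
    saturating = {
      if (params@gamma < 0) stop("'gamma' must be >= 0")
      (1 + params@gamma) * c / (1 + params@gamma * c)
    },
    polynomial = {
      (1 - params@p2 - params@p3) * c + params@p2 * c^2 + params@p3 * c^3
    },
    hill = ,
    hill_rise = {
      if (params@gamma < 0) stop("'gamma' must be >= 0")
      if (params@nHill <= 0) stop("'nHill' must be > 0")
      h <- function(x) {
        a <- (params@c0 + x)^params@nHill
        a / (a + (params@c0 + 1 / params@gamma)^params@nHill)
      }
      (h(c) - h(0)) / (h(1) - h(0))
    },
    stop("unknown probe type: ", params@probe))
}

#' One-step bound-probe evolution (hill_rise probe)
#'
#' First-order relaxation of the normalized bound-probe fraction towards its
#' calcium-dependent steady state \eqn{g_{hill}(c)} with time constant
#' \eqn{\tau_{on}}: \eqn{p' = p + (1-e^{-dt/\tau_{on}})(g_{hill}(c) - p)}.
#' The exact exponential relaxation factor is used, so the update is
#' unconditionally stable for any \eqn{dt/\tau_{on}} (no sub-stepping
#' needed); with \eqn{\tau_{on}=0} it returns \eqn{g_{hill}(c)} exactly.
#'
#' @param p current bound fraction (vectorized).
#' @param c normalized calcium over the step (vectorized).
#' @param dt frame interval (s).
#' @param params a [ModelParams-class] with \code{probe = "hill_rise"}.
#' @return updated bound fraction.
#' @export
evolveProbe <- function(p, c, dt, params) {
  stopifnot(params@probe == "hill_rise", dt > 0)
  gs <- probeResponse(c, params)
  if (params@tauOn == 0) return(gs)
  p + (1 - exp(-dt / params@tauOn)) * (gs - p)
}

#' Noiseless fluorescence measurement
#'
#' Maps a latent state to its noiseless fluorescence: the product of the
#' baseline with the nonlinear calcium response, \eqn{F = B(1 + A\,g(c))}
#' (or \eqn{B(1 + A\,p)} for the \code{hill_rise} probe, where \eqn{p} is
#' the bound-probe fraction).  In these relative units the resting
#' fluorescence equals the baseline, approximately 1.
#'
#' @param calcium normalized calcium (vectorized).
#' @param baseline baseline level (vectorized or scalar).
#' @param params a [ModelParams-class].
#' @param bound bound-probe fraction (required for \code{hill_rise}).
#' @return noiseless fluorescence in relative units.
#' @examples
#' measureFluo(1, 0.9, modelParams(A = 0.1))  # 0.99
#' @export
measureFluo <- function(calcium, baseline = 1, params, bound = NULL) {
  resp <- if (params@probe == "hill_rise") {
    if (is.null(bound)) stop("'bound' required for probe 'hill_rise'")
    bound
  } else probeResponse(calcium, params)
  baseline * (1 + params@A * resp)
}

#' Simulate a fluorescence trace from a spike train
#'
#' Bins the spikes at the frame interval (after shifting them by the probe
#' onset delay), iterates the calcium/probe evolution and the measurement
#' function, then adds a baseline random walk of amplitude \eqn{\eta} and
#' measurement noise.  Measurement noise is either white with SD
#' \code{params@sigma}, or, when a [NoiseSpec-class] is supplied, a
#' coloured series scaled so that its 0.1--3 Hz band RMS divided by \eqn{A}
#' equals the requested level (see [scaleNoiseToLevel()]).
#'
#' @param spikes a [SpikeTrain-class] or numeric vector of spike times (s),
#'   all within \code{[0, duration)}.
#' @param params a [ModelParams-class].
#' @param duration trace duration (s).
#' @param dt frame interval (s).
#' @param noise optional [NoiseSpec-class]; when given it replaces the white
#'   measurement noise (sigma is ignored for generation).
#' @param seed optional integer seed; the simulation is deterministic given
#'   the seed.
#' @param baseline initial baseline level (default 1).
#' @return a list with elements \code{trace} ([FluoTrace-class]),
#'   \code{path} ([LatentPath-class]) and \code{noiseless} (numeric vector).
#' @examples
#' sim <- simulateTrace(spikeTrain(c(1, 2.5)), modelParams(A = 0.1, tau = 1),
#'                      duration = 5, dt = 0.01, seed = 1)
#' @export
simulateTrace <- function(spikes, params, duration, dt, noise = NULL,
                          seed = NULL, baseline = 1) {
  times <- spikeTimes(spikes)
  if (length(times) && (min(times) < 0 || max(times) >= duration))
    stop("spike times must lie within [0, duration)")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  times <- times + params@delay
  times <- times[times < duration]
  nT <- as.integer(round(duration / dt))
  counts <- binSpikeTimes(times, dt, duration)
  length(counts) <- nT
  counts[is.na(counts)] <- 0L

  decay <- exp(-dt / params@tau)
  cpath <- numeric(nT)
  cc <- 0
  for (k in seq_len(nT)) {
    cc <- cc * decay + counts[k]
    cpath[k] <- cc
  }
  bound <- numeric(0)
  if (params@probe == "hill_rise") {
    bound <- numeric(nT)
    pp <- 0
    relax <- if (params@tauOn == 0) 1 else 1 - exp(-dt / params@tauOn)
    gs <- probeResponse(cpath, params)
    for (k in seq_len(nT)) {
      pp <- pp + relax * (gs[k] - pp)
      bound[k] <- pp
    }
  }
  B <- rep(baseline, nT)
  if (params@eta > 0) {
    steps <- params@eta * sqrt(dt) * stats::rnorm(nT - 1)
    B <- baseline + c(0, cumsum(steps))
    B <- abs(B)  # reflect at zero to keep the baseline positive
  }
  noiseless <- measureFluo(cpath, B, params,
                           bound = if (length(bound)) bound else NULL)
  eps <- if (is.null(noise)) {
    if (params@sigma > 0) stats::rnorm(nT, 0, params@sigma) else numeric(nT)
  } else {
    u <- genNoise(noise@kind, nT, dt)
    scaleNoiseToLevel(u, noise@level, params@A, dt, noise@band)
  }
  list(trace = fluoTrace(noiseless + eps, dt = dt),
       path = new("LatentPath", calcium = cpath, baseline = B,
                  bound = bound),
       noiseless = noiseless)
}
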