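#' @include methods.R
NULL

#' Generate a homogeneous Poisson spike train
#'
#' @param rate mean spike rate (spikes/s, \eqn{\ge 0}).
#' @param duration train duration (s).
#' @param seed optional integer seed for reproducibility.
#' @return a [SpikeTrain-class] with times in \code{[0, duration)}.
#' @examples
#' genPoissonTrain(1, 30, seed = 1)
#' @export
genPoissonTrain <- function(rate, duration, seed = NULL) {
  if (rate < 0) stop("'rate' must be >= 0")
  stopifnot(duration > 0)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  n <- stats::rpois(1, rate * duration)
  spikeTrain(sort(stats::runif(n, 0, duration)))
}

#' Generate a bursty spike train
#'
#' Burst events occur as a homogeneous Poisson process; each event carries a
#' geometrically distributed number of spikes with mean 1 (0 allowed, the
#' discrete analogue of an exponential law), and inter-spike intervals
#' within an event are Gaussian with mean 10 ms (negative draws resampled).
#'
#' @param eventRate mean burst-event rate (events/s).
#' @param duration train duration (s).
#' @param seed optional integer seed.
#' @param isiMean mean within-burst inter-spike interval (s).
#' @param isiSd SD of the within-burst interval (s); the value is not
#'   critical and defaults to 3 ms.
#' @return a [SpikeTrain-class], times sorted and clipped to
#'   \code{[0, duration)}.
#' @export
genBurstyTrain <- function(eventRate, duration, seed = NULL,
                           isiMean = 0.010, isiSd = 0.003) {
  if (eventRate < 0) stop("'eventRate' must be >= 0")
  stopifnot(duration > 0)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  nEv <- stats::rpois(1, eventRate * duration)
  if (nEv == 0) return(spikeTrain(numeric(0)))
  evTimes <- stats::runif(nEv, 0, duration)
  nSp <- stats::rgeom(nEv, 0.5)  # mean (1-p)/p = 1, zero allowed
  times <- unlist(lapply(seq_len(nEv), function(i) {
    if (nSp[i] == 0) return(numeric(0))
    if (nSp[i] == 1) return(evTimes[i])
    isi <- stats::rnorm(nSp[i] - 1, isiMean, isiSd)
    while (any(isi <= 0)) {
      bad <- isi <= 0
      isi[bad] <- stats::rnorm(sum(bad), isiMean, isiSd)
    }
    evTimes[i] + c(0, cumsum(isi))
  }))
  spikeTrain(sort(times[times < duration & times >= 0]))
}

#' Generate a unit-variance noise series
#'
#' Three regimes: \code{"white"} (i.i.d. Gaussian), \code{"white_plus_drift"}
#' (white noise plus a slow baseline-like drift: a random walk low-passed
#' below \code{lpCutoff}), and \code{"pink"} (1/f power spectrum synthesized
#' by frequency-domain shaping with random phases and zero DC).  The sample
#' variance of the returned series is normalized to exactly 1.
#'
#' @param kind noise regime.
#' @param n number of samples (\eqn{\ge 2}).
#' @param dt sample interval (s).
#' @param seed optional integer seed.
#' @param lpCutoff drift low-pass cutoff (Hz) for
#'   \code{"white_plus_drift"}.
#' @param mix total-RMS ratio of the drift component relative to the white
#'   component (drift regime; the mixture is not prescribed by the noise
#'   definition and defaults to 1).
#' @return numeric vector of length \code{n} with sample variance 1.
#' @examples
#' x <- genNoise("pink", 4096, 0.01, seed = 1)
#' var(x)  # 1
#' @export
genNoise <- function(kind = c("white", "white_plus_drift", "pink"), n,
                     dt, seed = NULL, lpCutoff = 0.1, mix = 1) {
  kind <- match.arg(kind)
  stopifnot(n >= 2, dt > 0)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  x <- switch(kind,
    white = stats::rnorm(n),
    pink = {
      f <- seq_len(n - 1) / (n * dt)       # positive+negative freqs, no DC
      half <- floor(n / 2)
      amp <- numeric(n)                     # spectral amplitudes, DC = 0
      amp[2:(half + 1)] <- 1 / sqrt(f[1:half])
      spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * amp
      # enforce Hermitian symmetry so the inverse transform is real
      spec[1] <- 0
      idx <- 2:ceiling((n + 1) / 2)
      spec[n + 2 - idx] <- Conj(spec[idx])
      if (n %% 2 == 0) spec[half + 1] <- Re(spec[half + 1])
      Re(stats::fft(spec, inverse = TRUE)) / n
    },
    white_plus_drift = {
      w <- stats::rnorm(n)
      rw <- cumsum(stats::rnorm(n))
      drift <- fftLowpass(rw, dt, lpCutoff)
      sw <- stats::sd(w)
      sdrift <- stats::sd(drift)
      if (sdrift > 0) drift <- drift * (mix * sw / sdrift)
      w + drift
    })
  x <- x - mean(x)
  x / sqrt(stats::var(x))
}

## internal: ideal (FFT-mask) low-pass filter below 'cutoff' Hz
fftLowpass <- function(x, dt, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)                  # folded (two-sided) frequencies
  X[f > cutoff] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

## internal: ideal band-pass via periodogram masking, keeps [lo, hi] Hz
fftBandpass <- function(x, dt, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Band-limited RMS of a series
#'
#' Square root of the summed periodogram power within a frequency band
#' (Parseval-consistent): for white noise of SD \eqn{\sigma} sampled at
#' \eqn{f_s}, the band \eqn{[f_1, f_2]} RMS is approximately
#' \eqn{\sigma\sqrt{2(f_2-f_1)/f_s}}, and a pure in-band sinusoid of
#' amplitude \eqn{a} gives \eqn{a/\sqrt{2}}.
#'
#' @param x numeric series.
#' @param dt sample interval (s).
#' @param band \code{c(f_lo, f_hi)} in Hz, within \code{(0, Nyquist]}.
#' @return scalar band RMS, in the units of \code{x}.
#' @examples
#' t <- seq(0, 20, by = 0.01)
#' bandRMS(sin(2 * pi * t), 0.01, c(0.1, 3))  # about 1/sqrt(2)
#' @export
bandRMS <- function(x, dt, band = c(0.1, 3)) {
  n <- length(x)
  stopifnot(n >= 2, dt > 0, length(band) == 2)
  nyq <- 1 / (2 * dt)
  if (band[1] <= 0 || band[2] > nyq + 1e-12 || band[2] <= band[1])
    stop("'band' must satisfy 0 < f_lo < f_hi <= Nyquist")
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / (n * dt)
  f <- pmin(f, 1 / dt - f)
  inband <- f >= band[1] & f <= band[2]
  sqrt(sum(Mod(X[inband])^2)) / n
}

#' Scale a noise series to a target band-RMS noise level
#'
#' The noise level of a series is its RMS power in the 0.1--3 Hz band
#' divided by the unitary transient amplitude \eqn{A}.  This function
#' rescales a series so that its realized (periodogram) band RMS divided by
#' \eqn{A} equals \code{level} exactly.
#'
#' @param noise numeric series (any scale).
#' @param level target noise level (\eqn{\ge 0}).
#' @param A unitary transient amplitude (\eqn{\Delta F/F}).
#' @param dt sample interval (s).
#' @param band measurement band (Hz).
#' @return the rescaled series.
#' @examples
#' x <- genNoise("white", 1024, 0.01, seed = 1)
#' y <- scaleNoiseToLevel(x, 0.2, 0.1, 0.01)
#' bandRMS(y, 0.01) / 0.1   # 0.2
#' @export
scaleNoiseToLevel <- function(noise, level, A, dt, band = c(0.1, 3)) {
  if (level < 0) stop("'level' must be >= 0")
  if (level == 0) return(numeric(length(noise)))
  r <- bandRMS(noise, dt, band)
  if (r == 0) stop("noise series has no power in the band")
  noise * (level * A / r)
}
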