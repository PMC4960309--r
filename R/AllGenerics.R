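#' @include AllClasses.R
NULL

#' Spike times of an object
#'
#' @param x a [SpikeTrain-class], [MapResult-class] or numeric vector.
#' @param ... unused.
#' @return numeric vector of spike times (s), sorted ascending.
#' @export
setGeneric("spikeTimes", function(x, ...) standardGeneric("spikeTimes"))

#' Number of spikes
#' @param x a [SpikeTrain-class] or [MapResult-class].
#' @return integer spike count.
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' Per-bin spike counts
#'
#' @param x a [SpikeTrain-class] or [MapResult-class].
#' @param dt bin width (s); defaults to the stored bin width when present.
#' @param duration total duration (s); defaults to cover the last spike.
#' @return integer vector of counts per bin.
#' @export
setGeneric("spikeCounts", function(x, dt = NULL, duration = NULL)
  standardGeneric("spikeCounts"))

#' Trace values
#' @param x a [FluoTrace-class] or [MapResult-class] (returns the fit).
#' @return numeric vector of per-frame fluorescence values.
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))

#' Frame interval
#' @param x an object carrying a frame interval.
#' @return the frame interval (s).
#' @export
setGeneric("frameDt", function(x) standardGeneric("frameDt"))

#' Duration of an object in seconds
#' @param x a [FluoTrace-class] or [SpikeTrain-class].
#' @return duration (s).
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Latent path of a result
#' @param x a [MapResult-class].
#' @return a [LatentPath-class].
#' @export
setGeneric("latentPath", function(x) standardGeneric("latentPath"))

#' Log posterior of a decoded path
#' @param x a [MapResult-class].
#' @return scalar log posterior (unnormalized).
#' @export
setGeneric("logPosterior", function(x) standardGeneric("logPosterior"))

#' Per-bin posterior spike-count probabilities
#' @param x a [SpikePosterior-class].
#' @return matrix T x (nmax+1) of probabilities \eqn{P(n_t=k|y)}.
#' @export
setGeneric("spikeMarginals", function(x) standardGeneric("spikeMarginals"))

#' Error rate of an evaluation report
#' @param x an [EvalReport-class].
#' @return scalar in [0, 1]: 1 minus the F1 score.
#' @export
setGeneric("errorRate", function(x) standardGeneric("errorRate"))
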