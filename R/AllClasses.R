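#' @import methods
NULL

PROBE_TYPES <- c("linear", "saturating", "polynomial", "hill", "hill_rise")

#' Generative-model parameters
#'
#' Container for all parameters of the generative model linking a spike train
#' to a fluorescence trace.  Calcium is tracked in normalized units (0 at
#' rest, +1 per action potential) and fluorescence in relative \eqn{\Delta
#' F/F} units where the resting baseline is approximately 1.
#'
#' @slot A unitary transient amplitude: \eqn{\Delta F/F} increase for one
#'   spike (e.g. 0.1 for 10\%).
#' @slot tau calcium decay time constant (s).
#' @slot probe probe nonlinearity, one of \code{"linear"},
#'   \code{"saturating"} (dye saturation, e.g. OGB), \code{"polynomial"}
#'   (cubic GECI supra-linearity), \code{"hill"} (cooperative binding),
#'   \code{"hill_rise"} (Hill binding with finite rise time).
#' @slot gamma saturation parameter: inverse of the number of spikes at which
#'   the dye reaches half saturation (saturating/hill probes).
#' @slot p2,p3 polynomial coefficients (polynomial probe).
#' @slot nHill Hill exponent (hill/hill_rise probes).
#' @slot c0 normalized resting calcium, in spike-equivalent units.
#' @slot tauOn probe binding time constant (s; hill_rise probe).
#' @slot delay fixed spike-to-onset delay (s); 0.02 for GCaMP6s, 0.01 for
#'   GCaMP6f.
#' @slot sigma measurement white-noise SD per sample (\eqn{\Delta F/F}).
#' @slot eta baseline drift amplitude (\eqn{\Delta F/F\,s^{-1/2}}).
#' @slot lam a priori spike rate (spikes/s).
#' @slot nmax maximum number of spikes per time bin.
#' @seealso [modelParams()], [probeProfile()]
#' @export
setClass("ModelParams",
  representation(
    A = "numeric", tau = "numeric", probe = "character",
    gamma = "numeric", p2 = "numeric", p3 = "numeric",
    nHill = "numeric", c0 = "numeric", tauOn = "numeric",
    delay = "numeric", sigma = "numeric", eta = "numeric",
    lam = "numeric", nmax = "integer"
  ),
  prototype(
    A = 0.1, tau = 1, probe = "linear", gamma = 0.1, p2 = 0.73,
    p3 = -0.05, nHill = 2, c0 = 0, tauOn = 0, delay = 0,
    sigma = 0.02, eta = 0, lam = 0.1, nmax = 3L
  )
)

setValidity("ModelParams", function(object) {
  msg <- character()
  chk1 <- function(x, nm) if (length(slot(object, x)) != 1 || !is.finite(slot(object, x)))
    sprintf("'%s' must be a finite scalar", x) else NULL
  for (s in c("A", "tau", "gamma", "p2", "p3", "nHill", "c0", "tauOn",
              "delay", "sigma", "eta", "lam"))
    msg <- c(msg, chk1(s))
  if (length(msg)) return(msg)
  if (object@A <= 0) msg <- c(msg, "'A' must be > 0")
  if (object@tau <= 0) msg <- c(msg, "'tau' must be > 0")
  if (object@gamma < 0) msg <- c(msg, "'gamma' must be >= 0")
  if (object@sigma < 0) msg <- c(msg, "'sigma' must be >= 0")
  if (object@eta < 0) msg <- c(msg, "'eta' must be >= 0")
  if (object@lam <= 0) msg <- c(msg, "'lam' must be > 0")
  if (object@delay < 0) msg <- c(msg, "'delay' must be >= 0")
  if (object@tauOn < 0) msg <- c(msg, "'tauOn' must be >= 0")
  if (object@nHill <= 0) msg <- c(msg, "'nHill' must be > 0")
  if (object@c0 < 0) msg <- c(msg, "'c0' must be >= 0")
  if (object@nmax < 1L) msg <- c(msg, "'nmax' must be >= 1")
  if (!object@probe %in% PROBE_TYPES)
    msg <- c(msg, paste0("'probe' must be one of: ",
                         paste(PROBE_TYPES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A spike train
#'
#' Spike times in seconds, sorted ascending.  When the train was produced by
#' binned inference, the per-bin counts and bin width are retained as well.
#'
#' @slot times ascending spike times (s).  A spike occurring \eqn{k} times in
#'   one bin appears \eqn{k} times.
#' @slot counts optional per-bin spike counts (integer, one per frame).
#' @slot dt bin width (s) for \code{counts}; \code{numeric(0)} when unused.
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", counts = "integer", dt = "numeric"),
  prototype(times = numeric(0), counts = integer(0), dt = numeric(0))
)

setValidity("SpikeTrain", function(object) {
  msg <- character()
  if (is.unsorted(object@times)) msg <- c(msg, "'times' must be sorted ascending")
  if (any(!is.finite(object@times))) msg <- c(msg, "'times' must be finite")
  if (length(object@counts) && any(object@counts < 0L))
    msg <- c(msg, "'counts' must be non-negative")
  if (length(object@counts) && (length(object@dt) != 1 || object@dt <= 0))
    msg <- c(msg, "'dt' must be a positive scalar when 'counts' is set")
  if (length(msg)) msg else TRUE
})

#' A fluorescence trace
#'
#' A single-neuron fluorescence time series in relative (\eqn{\Delta F/F})
#' units sampled at a fixed frame interval.
#'
#' @slot values fluorescence per frame (relative units, resting level near 1
#'   after baseline normalization, or \eqn{\Delta F/F} near 0 -- the model
#'   works in units where the resting baseline is about 1).
#' @slot dt frame interval (s).
#' @export
setClass("FluoTrace",
  representation(values = "numeric", dt = "numeric"),
  prototype(values = numeric(0), dt = 0.01)
)

setValidity("FluoTrace", function(object) {
  msg <- character()
  if (length(object@dt) != 1 || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a positive scalar")
  if (any(!is.finite(object@values))) msg <- c(msg, "'values' must be finite")
  if (length(msg)) msg else TRUE
})

#' Latent state path
#'
#' Per-frame values of the hidden state: normalized calcium, baseline, and
#' (for the \code{hill_rise} probe) the normalized bound-probe fraction.
#'
#' @slot calcium normalized calcium per frame (0 at rest, +1 per spike).
#' @slot baseline baseline per frame (relative units, about 1).
#' @slot bound normalized bound-probe fraction per frame (\code{hill_rise}
#'   only; otherwise empty).
#' @export
setClass("LatentPath",
  representation(calcium = "numeric", baseline = "numeric", bound = "numeric"),
  prototype(calcium = numeric(0), baseline = numeric(0), bound = numeric(0))
)

setValidity("LatentPath", function(object) {
  msg <- character()
  if (any(object@calcium < 0)) msg <- c(msg, "'calcium' must be >= 0")
  if (length(object@baseline) && any(object@baseline <= 0))
    msg <- c(msg, "'baseline' must be > 0")
  if (length(object@bound) &&
      length(object@bound) != length(object@calcium))
    msg <- c(msg, "'bound' must match 'calcium' in length")
  if (length(msg)) msg else TRUE
})

#' Noise specification for simulated traces
#'
#' @slot kind one of \code{"white"}, \code{"white_plus_drift"},
#'   \code{"pink"}.
#' @slot level band-RMS noise level in units of the unitary amplitude
#'   \eqn{A}: RMS power of the noise in \code{band}, divided by \eqn{A}.
#' @slot band frequency band (Hz) over which the level is measured; default
#'   \code{c(0.1, 3)}.
#' @export
setClass("NoiseSpec",
  representation(kind = "character", level = "numeric", band = "numeric"),
  prototype(kind = "white", level = 0.1, band = c(0.1, 3))
)

setValidity("NoiseSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("white", "white_plus_drift", "pink"))
    msg <- c(msg, "'kind' must be white, white_plus_drift or pink")
  if (length(object@level) != 1 || object@level < 0)
    msg <- c(msg, "'level' must be a non-negative scalar")
  if (length(object@band) != 2 || object@band[1] < 0 ||
      object@band[2] <= object@band[1])
    msg <- c(msg, "'band' must be increasing c(f_lo, f_hi) with f_lo >= 0")
  if (length(msg)) msg else TRUE
})

#' Discretized state grid for inference
#'
#' Internal representation of the discretization of the hidden state space
#' (calcium, optionally bound probe, baseline) together with precomputed
#' interpolation operators used by the recursions.  Built by
#' [buildStateGrid()]; users normally never construct it directly.
#'
#' @slot cValues ascending calcium grid values.
#' @slot bValues ascending baseline grid values.
#' @slot pValues ascending bound-probe grid values (\code{hill_rise} only).
#' @slot ops list of precomputed operators (interpolation matrices per spike
#'   count, emission means, log-priors, baseline step kernel).
#' @export
setClass("StateGrid",
  representation(cValues = "numeric", bValues = "numeric",
                 pValues = "numeric", ops = "list"),
  prototype(cValues = numeric(0), bValues = 1, pValues = numeric(0),
            ops = list())
)

setValidity("StateGrid", function(object) {
  msg <- character()
  if (length(object@cValues) < 2 || is.unsorted(object@cValues, strictly = TRUE))
    msg <- c(msg, "'cValues' must be >= 2 strictly increasing values")
  if (length(object@bValues) < 1 ||
      (length(object@bValues) > 1 && is.unsorted(object@bValues, strictly = TRUE)))
    msg <- c(msg, "'bValues' must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' MAP inference result
#'
#' @slot spikes the MAP spike train (with per-bin counts).
#' @slot path the decoded latent path (calcium, baseline).
#' @slot logPosterior unnormalized log posterior of the decoded path
#'   (transition priors plus emission terms; the flat initial-state prior
#'   contributes only a constant and is omitted).
#' @slot fit noiseless predicted fluorescence along the decoded path.
#' @slot dt frame interval (s).
#' @export
setClass("MapResult",
  representation(spikes = "SpikeTrain", path = "LatentPath",
                 logPosterior = "numeric", fit = "numeric", dt = "numeric"))

setValidity("MapResult", function(object) {
  if (length(object@logPosterior) != 1 || !is.finite(object@logPosterior))
    "'logPosterior' must be a finite scalar" else TRUE
})

#' Posterior spike probabilities
#'
#' Result of forward--backward smoothing: per-bin posterior spike-count
#' probabilities and expected counts.
#'
#' @slot spikeMarginals matrix \eqn{T \times (nmax+1)}: column \eqn{k+1}
#'   holds \eqn{P(n_t = k \mid y)}.  Rows sum to 1 (bin 1 carries no spikes
#'   by convention).
#' @slot expected expected spike count per bin.
#' @slot logEvidence log marginal likelihood of the trace under the model
#'   (up to the flat initial-prior constant).
#' @slot alpha optional filtering distributions \eqn{p(x_t \mid
#'   y_{1..t})} as an array (calcium-state x baseline x time), kept only when
#'   requested in the control list.
#' @slot beta optional conditional likelihoods \eqn{p(y_{t..T} \mid x_t)}
#'   (each time slice normalized to maximum 1), same layout.
#' @slot dt frame interval (s).
#' @export
setClass("SpikePosterior",
  representation(spikeMarginals = "matrix", expected = "numeric",
                 logEvidence = "numeric", alpha = "array", beta = "array",
                 dt = "numeric"),
  prototype(alpha = array(0, c(0, 0, 0)), beta = array(0, c(0, 0, 0))))

setValidity("SpikePosterior", function(object) {
  rs <- rowSums(object@spikeMarginals)
  if (length(rs) && max(abs(rs - 1)) > 1e-9)
    "rows of 'spikeMarginals' must sum to 1" else TRUE
})

#' Autocalibration result
#'
#' @slot AHat estimated unitary amplitude (\eqn{\Delta F/F}).
#' @slot tauHat estimated decay time constant (s).
#' @slot sigmaHat estimated noise SD per session (\eqn{\Delta F/F}).
#' @slot events data.frame of calcium events used (time, amplitude, trial,
#'   assigned spike count).
#' @slot diagnostics list with the amplitude-histogram curves (x1, x2, x3)
#'   and intermediate values.
#' @slot fallback TRUE when no usable isolated events were found and the
#'   probe-profile default values were returned instead.
#' @export
setClass("CalibrationResult",
  representation(AHat = "numeric", tauHat = "numeric", sigmaHat = "numeric",
                 events = "data.frame", diagnostics = "list",
                 fallback = "logical"),
  prototype(fallback = FALSE))

setValidity("CalibrationResult", function(object) {
  msg <- character()
  if (object@tauHat <= 0) msg <- c(msg, "'tauHat' must be > 0")
  if (any(object@sigmaHat < 0)) msg <- c(msg, "'sigmaHat' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Spike-train matching result
#'
#' Minimum-cost, order-preserving, one-to-one alignment between a reference
#' and an estimated spike train.
#'
#' @slot pairs two-column matrix of matched (true time, estimated time).
#' @slot nMiss number of unmatched reference spikes.
#' @slot nFalse number of unmatched estimated spikes.
#' @slot tolerance matching tolerance (s): no matched pair is further apart.
#' @export
setClass("MatchResult",
  representation(pairs = "matrix", nMiss = "integer", nFalse = "integer",
                 tolerance = "numeric"))

setValidity("MatchResult", function(object) {
  msg <- character()
  if (ncol(object@pairs) != 2) msg <- c(msg, "'pairs' must have two columns")
  if (nrow(object@pairs) &&
      any(abs(object@pairs[, 1] - object@pairs[, 2]) >
          object@tolerance + 1e-12))
    msg <- c(msg, "matched pairs must be within 'tolerance'")
  if (length(msg)) msg else TRUE
})

#' Spike-train evaluation report
#'
#' @slot sensitivity fraction of true spikes detected.
#' @slot precision fraction of estimated spikes that are correct.
#' @slot er error rate: 1 minus the harmonic mean (F1) of sensitivity and
#'   precision.
#' @slot meanTemporalError mean |delay| over matched pairs (s; NA when no
#'   pairs).
#' @slot correlation Pearson correlation between binned true counts and the
#'   smoothed estimated rate (NA when not computed or undefined).
#' @slot noiseLevel band-RMS residual noise level (NA when not computed).
#' @slot counts named integer vector (nTrue, nEst, nMatch).
#' @export
setClass("EvalReport",
  representation(sensitivity = "numeric", precision = "numeric",
                 er = "numeric", meanTemporalError = "numeric",
                 correlation = "numeric", noiseLevel = "numeric",
                 counts = "integer"),
  prototype(meanTemporalError = NA_real_, correlation = NA_real_,
            noiseLevel = NA_real_))
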