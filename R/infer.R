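#' @include model.R
NULL

#' Inference engine control settings
#'
#' Tunable settings of the grid-based estimator.  The defaults follow the
#' standard configuration: 100 calcium and 100 baseline values (both can
#' usually be reduced to 30 without introducing estimation errors), calcium
#' range [0, 10] with square-root spacing (denser near rest to resolve
#' single spikes), baseline grid spanning +/-30\% around an initial estimate
#' (the 10th percentile of the trace), a 5-point local baseline search with
#' quadratic refinement, and uniform initial priors on calcium and
#' baseline.
#'
#' @param nc number of calcium grid values.
#' @param nb number of baseline grid values (1 fixes the baseline).
#' @param np number of bound-probe grid values (\code{hill_rise} only).
#' @param cmax calcium grid upper bound (spike-equivalent units).
#' @param bWidth half-width of the baseline grid, as a fraction of the
#'   initial baseline estimate.
#' @param bWindow number of grid values searched locally along the baseline
#'   (centered on the current value).
#' @param c1Prior prior on the initial calcium state: \code{"uniform"}
#'   over the grid (default) or \code{"rest"} (known resting start).
#' @param baseline optional known baseline level; with \code{eta = 0} this
#'   fixes the baseline exactly (sets \code{nb = 1}).
#' @param keepArrays keep the full filtering/likelihood arrays in
#'   [spikeProbabilities()] results (memory heavy on long traces).
#' @return a named list of settings.
#' @export
spikeControl <- function(nc = 100, nb = 100, np = 40, cmax = 10,
                         bWidth = 0.3, bWindow = 5,
                         c1Prior = c("uniform", "rest"), baseline = NULL,
                         keepArrays = FALSE) {
  list(nc = as.integer(nc), nb = as.integer(nb), np = as.integer(np),
       cmax = cmax, bWidth = bWidth, bWindow = as.integer(bWindow),
       c1Prior = match.arg(c1Prior), baseline = baseline,
       keepArrays = isTRUE(keepArrays))
}

probeCode <- function(probe)
  switch(probe, linear = 0L, saturating = 1L, polynomial = 2L,
         hill = 3L, hill_rise = 3L)

## second-derivative operator of the natural cubic spline on 'grid':
## M = C y solves the tridiagonal continuity system with M_1 = M_n = 0
splineCurvatureOp <- function(grid) {
  n <- length(grid)
  h <- diff(grid)
  if (n < 3) return(matrix(0, n, n))
  Tm <- matrix(0, n - 2, n - 2)
  B <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) {
    Tm[i, i] <- (h[i] + h[i + 1]) / 3
    if (i > 1) Tm[i, i - 1] <- h[i] / 6
    if (i < n - 2) Tm[i, i + 1] <- h[i + 1] / 6
    B[i, i] <- 1 / h[i]
    B[i, i + 1] <- -1 / h[i] - 1 / h[i + 1]
    B[i, i + 2] <- 1 / h[i + 1]
  }
  rbind(0, solve(Tm, B), 0)
}

## natural-cubic-spline interpolation matrix: row s holds the weights that
## evaluate a function known on 'grid' at query point x[s].  Assembled as
## (linear part) + (cubic part) %*% C, so the expensive solve in C is done
## once per grid and shared across query sets.
splineInterpMatrix <- function(grid, x, C = splineCurvatureOp(grid)) {
  n <- length(grid)
  x <- pmin(pmax(x, grid[1]), grid[n])
  i <- pmin(pmax(findInterval(x, grid), 1L), n - 1L)
  h <- grid[i + 1] - grid[i]
  u <- (grid[i + 1] - x) / h              # weight on the left knot
  v <- (x - grid[i]) / h
  W <- matrix(0, length(x), n)
  idx <- cbind(seq_along(x), i)
  W[idx] <- W[idx] + u
  idx2 <- cbind(seq_along(x), i + 1L)
  W[idx2] <- W[idx2] + v
  cu <- (u^3 - u) * h^2 / 6               # curvature weights
  cv <- (v^3 - v) * h^2 / 6
  W + cu * C[i, , drop = FALSE] + cv * C[i + 1, , drop = FALSE]
}

## local interpolation weights (cubic inside, linear at edges) as a sparse
## triplet list; queries clamped to the grid range
localInterpWeights <- function(grid, x) {
  n <- length(grid)
  x <- pmin(pmax(x, grid[1]), grid[n])
  i1 <- pmin(pmax(findInterval(x, grid), 1L), n - 1L)
  rows <- integer(0); cols <- integer(0); w <- numeric(0)
  for (s in seq_along(x)) {
    i <- i1[s]
    if (i == 1L || i == n - 1L) {
      u <- (x[s] - grid[i]) / (grid[i + 1] - grid[i])
      rows <- c(rows, s, s); cols <- c(cols, i, i + 1L)
      w <- c(w, 1 - u, u)
    } else {
      xs <- grid[(i - 1):(i + 2)]
      L <- vapply(1:4, function(a)
        prod((x[s] - xs[-a]) / (xs[a] - xs[-a])), 0)
      rows <- c(rows, rep(s, 4)); cols <- c(cols, (i - 1):(i + 2))
      w <- c(w, L)
    }
  }
  list(rows = rows, cols = cols, w = w)
}

#' Build the discretized state grid for a trace
#'
#' Discretizes the hidden state space and precomputes the operators used by
#' the recursions: per-spike-count (or per-event-amplitude) interpolation
#' matrices mapping grid functions of the next state to the current states'
#' children, the emission means, the truncated-Poisson spike prior and the
#' baseline step kernel.
#'
#' @param trace a [FluoTrace-class].
#' @param params a [ModelParams-class].
#' @param control a [spikeControl()] list.
#' @param jumps calcium jump values per candidate (default
#'   \code{0:params@nmax} spikes); calcium-event detection passes
#'   amplitudes here.
#' @param logJump log prior weight per candidate (default truncated
#'   \code{Poisson(lambda dt)} without renormalization, the truncated mass
#'   being negligible for \code{lambda*dt << 1}).
#' @return a [StateGrid-class].
#' @export
buildStateGrid <- function(trace, params, control = spikeControl(),
                           jumps = NULL, logJump = NULL) {
  dt <- trace@dt
  nc <- control$nc
  cValues <- control$cmax * (seq(0, 1, length.out = nc))^2
  decay <- exp(-dt / params@tau)
  if (is.null(jumps)) jumps <- 0:params@nmax
  if (is.null(logJump))
    logJump <- stats::dpois(0:params@nmax, params@lam * dt, log = TRUE)
  stopifnot(length(jumps) == length(logJump))

  ## baseline grid
  if (!is.null(control$baseline) && params@eta == 0) {
    bValues <- control$baseline
  } else {
    b0 <- if (!is.null(control$baseline)) control$baseline
          else as.numeric(stats::quantile(trace@values, 0.10))
    if (b0 <= 0) b0 <- max(mean(trace@values), .Machine$double.eps)
    bValues <- if (control$nb == 1) b0
               else seq(b0 * (1 - control$bWidth), b0 * (1 + control$bWidth),
                        length.out = control$nb)
  }
  nb <- length(bValues)

  hillRise <- params@probe == "hill_rise"
  if (!hillRise) {
    pValues <- numeric(0)
    g <- probeResponse(cValues, params)
    pred <- outer(1 + params@A * g, bValues)
    C <- splineCurvatureOp(cValues)
    W <- lapply(jumps, function(n)
      splineInterpMatrix(cValues, pmin(decay * cValues + n, control$cmax),
                         C = C))
  } else {
    np <- control$np
    ## the bound fraction relaxes towards g(c) <= g(cmax), so the grid only
    ## needs to cover that range; sqrt spacing resolves single spikes
    pmax <- probeResponse(control$cmax, params)
    pValues <- pmax * (seq(0, 1, length.out = np))^2
    S <- nc * np
    pred <- outer(rep(1 + params@A * pValues, each = nc), bValues)
    relax <- if (params@tauOn == 0) 1 else 1 - exp(-dt / params@tauOn)
    gC <- probeResponse(cValues, params)
    ## child coordinates per flattened state s = i + nc (k - 1)
    cIdxAll <- rep(seq_len(nc), np)
    pIdxAll <- rep(seq_len(np), each = nc)
    pChild <- pValues[pIdxAll] + relax * (gC[cIdxAll] - pValues[pIdxAll])
    wp <- localInterpWeights(pValues, pChild)  # 2 nnz per row (linear)
    W <- lapply(jumps, function(n) {
      cChild <- pmin(decay * cValues[cIdxAll] + n, control$cmax)
      wc <- localInterpWeights(cValues, cChild)
      ## combine: split triplets per row and take the tensor product
      rows <- integer(0); cols <- integer(0); vals <- numeric(0)
      wcr <- split(seq_along(wc$rows), wc$rows)
      wpr <- split(seq_along(wp$rows), wp$rows)
      for (s in seq_len(S)) {
        ic <- wcr[[s]]; ip <- wpr[[s]]
        cc <- wc$cols[ic]; cw <- wc$w[ic]
        pc <- wp$cols[ip]; pw <- wp$w[ip]
        colIdx <- rep(cc, times = length(pc)) +
          nc * (rep(pc, each = length(cc)) - 1L)
        vv <- rep(cw, times = length(pc)) * rep(pw, each = length(cc))
        rows <- c(rows, rep.int(s, length(vv)))
        cols <- c(cols, colIdx); vals <- c(vals, vv)
      }
      Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(S, S))
    })
  }

  ## baseline transition kernel (row-stochastic) for the sum passes
  G <- if (params@eta > 0 && nb > 1) {
    M <- outer(bValues, bValues,
               function(a, b) stats::dnorm(b - a, 0,
                                           params@eta * sqrt(dt)))
    M / rowSums(M)
  } else diag(nb)

  new("StateGrid", cValues = cValues, bValues = bValues, pValues = pValues,
      ops = list(W = W, pred = pred, logJump = logJump, jumps = jumps,
                 G = G, decay = decay, dt = dt,
                 relax = if (hillRise) {
                   if (params@tauOn == 0) 1 else 1 - exp(-dt / params@tauOn)
                 } else 0))
}

#' Log prior probability of a state transition
#'
#' Log probability of emitting \code{n} spikes in a bin plus the log density
#' of a baseline step: \eqn{\log Pois(n; \lambda \Delta t) + \log N(dB; 0,
#' \eta^2 \Delta t)}.  Counts above \code{nmax} (the per-bin cap, default 3)
#' have probability zero.
#'
#' @param n spike count(s).
#' @param dB baseline step(s).
#' @param params a [ModelParams-class].
#' @param dt frame interval (s).
#' @return log probability (\code{-Inf} beyond the cap).
#' @examples
#' transitionLogProb(0, 0, modelParams(lam = 0.1), dt = 0.01)
#' @export
transitionLogProb <- function(n, dB = 0, params, dt) {
  lp <- stats::dpois(n, params@lam * dt, log = TRUE)
  lp[n > params@nmax] <- -Inf
  if (params@eta > 0)
    lp <- lp + stats::dnorm(dB, 0, params@eta * sqrt(dt), log = TRUE)
  lp
}

#' Log likelihood of an observed fluorescence value
#'
#' Gaussian measurement model: \eqn{\log N(y; F(x), \sigma^2)} where
#' \eqn{F(x)} is the noiseless prediction of the state (see
#' [measureFluo()]).
#'
#' @param y observed fluorescence value(s).
#' @param calcium,baseline,bound latent state (see [measureFluo()]).
#' @param params a [ModelParams-class].
#' @return log likelihood; with \code{sigma = 0}, \code{Inf} where the
#'   observation equals the prediction and \code{-Inf} elsewhere.
#' @export
emissionLogProb <- function(y, calcium, baseline = 1, params, bound = NULL) {
  pred <- measureFluo(calcium, baseline, params, bound)
  if (params@sigma == 0) return(ifelse(y == pred, Inf, -Inf))
  stats::dnorm(y, pred, params@sigma, log = TRUE)
}

## internal: shared Viterbi run over an arbitrary candidate-jump set
runViterbi <- function(trace, params, control, grid = NULL, jumps = NULL,
                       logJump = NULL, refineJump = FALSE) {
  if (params@sigma <= 0) stop("'sigma' must be > 0 for inference")
  y <- trace@values
  if (any(!is.finite(y))) stop("trace contains non-finite values")
  if (length(y) < 2) stop("trace must have at least 2 frames")
  if (is.null(grid))
    grid <- buildStateGrid(trace, params, control, jumps, logJump)
  ops <- grid@ops
  etaSqDt <- params@eta^2 * trace@dt
  m <- .backwardPass(y, ops$pred, ops$W, ops$logJump, grid@bValues,
                     etaSqDt, params@sigma, control$bWindow, refineJump)
  if (any(!is.finite(m[, , 1]))) stop("numerical underflow in backward pass")
  fc <- .forwardCollect(m, y, grid@cValues, grid@pValues, grid@bValues,
                        ops$jumps, ops$logJump, etaSqDt, params@sigma,
                        control$bWindow, ops$decay, ops$relax,
                        probeCode(params@probe), params@A, params@gamma,
                        params@p2, params@p3, params@nHill, params@c0,
                        if (control$c1Prior == "rest") 1L else 0L,
                        refineJump)
  fc$grid <- grid
  fc
}

#' MAP spike-train estimation
#'
#' Estimates the single most probable spike train given a fluorescence
#' trace: a backward Viterbi-style recursion computes, on the discretized
#' (calcium, baseline) grid, the conditional best log probability
#' \eqn{m_t(x_t)} of the trajectory continuing optimally to the end of the
#' trace -- children of grid states are evaluated by natural-spline
#' interpolation along calcium and a local 5-point quadratic refinement
#' along the baseline -- and a single forward collecting sweep then reads
#' off the optimal spike counts, calcium and baseline paths.  All
#' computations are in log space.
#'
#' @param trace a [FluoTrace-class] (or numeric vector with \code{dt}).
#' @param params a [ModelParams-class]; \code{sigma} must be positive.
#' @param control a [spikeControl()] list.
#' @param dt frame interval when \code{trace} is numeric.
#' @param grid optional precomputed [buildStateGrid()] result (reused
#'   across calls on the same trace/parameters).
#' @return a [MapResult-class].  Estimated spike times are reported at bin
#'   midpoints, shifted backward by the probe onset delay.
#' @examples
#' p <- modelParams(A = 0.1, tau = 1, sigma = 0.02, lam = 0.5)
#' sim <- simulateTrace(spikeTrain(c(1, 2.2)), p, 4, 0.02, seed = 2)
#' fit <- mapSpikes(sim$trace, p, spikeControl(nc = 50, nb = 20))
#' spikeTimes(fit)
#' @export
mapSpikes <- function(trace, params, control = spikeControl(), dt = NULL,
                      grid = NULL) {
  if (!is(trace, "FluoTrace")) trace <- fluoTrace(trace, dt = dt)
  fc <- runViterbi(trace, params, control, grid = grid)
  counts <- as.integer(fc$counts)
  k <- rep.int(seq_along(counts), counts)
  times <- pmax((k - 1.5) * trace@dt - params@delay, 0)
  st <- new("SpikeTrain", times = times, counts = counts, dt = trace@dt)
  path <- new("LatentPath", calcium = as.numeric(fc$calcium),
              baseline = as.numeric(fc$baseline),
              bound = as.numeric(fc$bound))
  fit <- measureFluo(path@calcium, path@baseline, params,
                     bound = if (length(path@bound)) path@bound else NULL)
  new("MapResult", spikes = st, path = path,
      logPosterior = fc$logPosterior, fit = fit, dt = trace@dt)
}

#' Posterior spike probabilities by forward-backward smoothing
#'
#' Replaces the maximizations of the MAP recursion with sums: a backward
#' pass computes \eqn{p(y_t..y_T \mid x_t)} and a forward filtering pass
#' \eqn{p(x_t \mid y_1..y_t)} on the same grid (with per-step
#' normalization), from which the posterior probability of each spike count
#' in each bin and the expected spike count are obtained.
#'
#' @inheritParams mapSpikes
#' @return a [SpikePosterior-class].
#' @export
spikeProbabilities <- function(trace, params, control = spikeControl(),
                               dt = NULL, grid = NULL) {
  if (!is(trace, "FluoTrace")) trace <- fluoTrace(trace, dt = dt)
  if (params@sigma <= 0) stop("'sigma' must be > 0 for inference")
  if (is.null(grid)) grid <- buildStateGrid(trace, params, control)
  pois <- exp(grid@ops$logJump)
  res <- .sumPass(trace@values, grid@ops$pred, grid@ops$W, pois,
                  grid@ops$G, params@sigma,
                  if (control$c1Prior == "rest") 1L else 0L,
                  control$keepArrays)
  marg <- res$marginals
  colnames(marg) <- paste0("n", seq_len(ncol(marg)) - 1)
  expected <- as.numeric(marg %*% (seq_len(ncol(marg)) - 1))
  new("SpikePosterior", spikeMarginals = marg, expected = expected,
      logEvidence = res$logEvidence,
      alpha = if (control$keepArrays) res$alpha else array(0, c(0, 0, 0)),
      beta = if (control$keepArrays) res$beta else array(0, c(0, 0, 0)),
      dt = trace@dt)
}

#' Sample spike trains from the posterior
#'
#' Computes the backward conditional likelihoods \eqn{p(y_t..y_T \mid x_t)}
#' and then draws state sequences ancestrally: the initial state from
#' \eqn{p(x_1) p(y \mid x_1)}, each next state from the transition prior
#' reweighted by the backward likelihood.  Reproducible given the seed.
#'
#' @inheritParams mapSpikes
#' @param nSamples number of posterior sample trains.
#' @param seed optional integer seed.
#' @param keepPaths also return the sampled calcium/baseline paths.
#' @return a list with \code{counts} (T x nSamples matrix of per-bin spike
#'   counts), \code{trains} (list of [SpikeTrain-class]) and, optionally,
#'   \code{paths} (list of [LatentPath-class]).
#' @export
samplePosterior <- function(trace, params, control = spikeControl(),
                            nSamples = 100, seed = NULL, dt = NULL,
                            keepPaths = FALSE) {
  if (!is(trace, "FluoTrace")) trace <- fluoTrace(trace, dt = dt)
  if (params@sigma <= 0) stop("'sigma' must be > 0 for inference")
  stopifnot(nSamples >= 1)
  if (params@probe == "hill_rise")
    stop("posterior sampling is not supported for the hill_rise probe")
  grid <- buildStateGrid(trace, params, control)
  pois <- exp(grid@ops$logJump)
  res <- .sumPass(trace@values, grid@ops$pred, grid@ops$W, pois,
                  grid@ops$G, params@sigma,
                  if (control$c1Prior == "rest") 1L else 0L, FALSE)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  smp <- .samplePass(res$beta, grid@ops$W, pois, grid@ops$G,
                     if (control$c1Prior == "rest") 1L else 0L,
                     as.integer(nSamples), isTRUE(keepPaths))
  counts <- smp$counts
  trains <- lapply(seq_len(ncol(counts)), function(r) {
    cts <- as.integer(counts[, r])
    k <- rep.int(seq_along(cts), cts)
    new("SpikeTrain", times = pmax((k - 1.5) * trace@dt - params@delay, 0),
        counts = cts, dt = trace@dt)
  })
  out <- list(counts = counts, trains = trains)
  if (keepPaths)
    out$paths <- lapply(seq_len(ncol(counts)), function(r)
      new("LatentPath", calcium = grid@cValues[smp$cIndex[, r] + 1],
          baseline = grid@bValues[smp$bIndex[, r] + 1]))
  out
}

## internal: exact log posterior of a given path (counts from bin 2 on,
## c1 initial calcium, B constant or per-bin), excluding the flat
## initial-state prior constant
pathLogPosterior <- function(y, dt, params, counts, c1 = 0, B = 1) {
  T <- length(y)
  decay <- exp(-dt / params@tau)
  cc <- numeric(T); cc[1] <- c1
  for (t in 2:T) cc[t] <- cc[t - 1] * decay + counts[t]
  if (length(B) == 1) B <- rep(B, T)
  lp <- sum(stats::dpois(counts[2:T], params@lam * dt, log = TRUE))
  if (params@eta > 0)
    lp <- lp + sum(stats::dnorm(diff(B), 0, params@eta * sqrt(dt),
                                log = TRUE))
  pred <- measureFluo(cc, B, params)
  lp + sum(stats::dnorm(y, pred, params@sigma, log = TRUE))
}

#' Exhaustive MAP search (test oracle)
#'
#' Enumerates every admissible spike-count sequence (and, optionally, every
#' baseline grid path), evaluates the exact log posterior of each and
#' returns the maximum.  Exponential in the number of bins -- usable only
#' on small instances; a cap on the search-space size guards against
#' accidental blow-up.
#'
#' @param trace a [FluoTrace-class] or numeric vector.
#' @param params a [ModelParams-class].
#' @param c1Values candidate initial calcium values (default 0: resting
#'   start).
#' @param bValues candidate baseline values: a single value fixes the
#'   baseline; several values with \code{eta > 0} enumerate full baseline
#'   paths on that grid.
#' @param nmax per-bin spike cap (default from \code{params}).
#' @param maxPaths search-space cap (default \code{2^21}).
#' @param dt frame interval for numeric traces.
#' @return list with \code{counts}, \code{c1}, \code{baseline},
#'   \code{logPosterior}.
#' @export
bruteForceMap <- function(trace, params, c1Values = 0, bValues = 1,
                          nmax = params@nmax, maxPaths = 2^21, dt = NULL) {
  enum <- bruteForceEnumerate(trace, params, c1Values, bValues, nmax,
                              maxPaths, dt)
  i <- which.max(enum$lp)
  list(counts = c(0L, enum$ns[enum$seqIdx[i], ]),
       c1 = enum$c1[i], baseline = enum$B[enum$bIdx[i], ],
       logPosterior = enum$lp[i])
}

#' Exhaustive smoothing posterior (test oracle)
#'
#' Same enumeration as [bruteForceMap()], but sums posterior weights to
#' produce the exact per-bin spike-count marginals
#' \eqn{P(n_t = k \mid y)}.
#'
#' @inheritParams bruteForceMap
#' @return matrix T x (nmax+1) of marginal probabilities (first row is the
#'   no-spike convention for bin 1).
#' @export
bruteForcePosterior <- function(trace, params, c1Values = 0, bValues = 1,
                                nmax = params@nmax, maxPaths = 2^21,
                                dt = NULL) {
  enum <- bruteForceEnumerate(trace, params, c1Values, bValues, nmax,
                              maxPaths, dt)
  w <- exp(enum$lp - max(enum$lp))
  w <- w / sum(w)
  T <- ncol(enum$ns) + 1L
  marg <- matrix(0, T, nmax + 1)
  marg[1, 1] <- 1
  for (t in 2:T) {
    nt <- enum$ns[enum$seqIdx, t - 1]
    for (k in 0:nmax) marg[t, k + 1] <- sum(w[nt == k])
  }
  colnames(marg) <- paste0("n", 0:nmax)
  marg
}

## internal: shared enumerator over (spike sequence, c1, baseline path)
bruteForceEnumerate <- function(trace, params, c1Values, bValues, nmax,
                                maxPaths, dt = NULL) {
  if (is(trace, "FluoTrace")) { y <- trace@values; dt <- trace@dt }
  else { y <- as.numeric(trace); stopifnot(!is.null(dt)) }
  T <- length(y)
  stopifnot(T >= 2)
  bPath <- params@eta > 0 && length(bValues) > 1
  nSeq <- (nmax + 1)^(T - 1)
  nB <- if (bPath) length(bValues)^T else length(bValues)
  if (nSeq * length(c1Values) * nB > maxPaths)
    stop("search space exceeds 'maxPaths'")
  ns <- as.matrix(expand.grid(rep(list(0:nmax), T - 1)))
  storage.mode(ns) <- "integer"
  decay <- exp(-dt / params@tau)
  lpn <- rowSums(matrix(stats::dpois(ns, params@lam * dt, log = TRUE),
                        nrow(ns)))
  B <- if (bPath) as.matrix(expand.grid(rep(list(bValues), T)))
       else matrix(bValues, ncol = 1)
  lpB <- if (bPath)
    rowSums(matrix(stats::dnorm(t(diff(t(B))), 0,
                                params@eta * sqrt(dt), log = TRUE),
                   nrow(B)))
  else numeric(nrow(B))
  ## expand over c1 and baseline alternatives
  lpAll <- c(); seqIdx <- c(); c1All <- c(); bIdx <- c()
  for (c1 in c1Values) {
    cc <- matrix(0, nrow(ns), T)
    cc[, 1] <- c1
    for (t in 2:T) cc[, t] <- cc[, t - 1] * decay + ns[, t - 1]
    g <- matrix(probeResponse(as.vector(cc), params), nrow(ns))
    for (b in seq_len(nrow(B))) {
      Bt <- if (ncol(B) == 1) rep(B[b, 1], T) else B[b, ]
      pred <- sweep(1 + params@A * g, 2, Bt, "*")
      ll <- rowSums(stats::dnorm(matrix(y, nrow(ns), T, byrow = TRUE),
                                 pred, params@sigma, log = TRUE))
      lpAll <- c(lpAll, lpn + lpB[b] + ll)
      seqIdx <- c(seqIdx, seq_len(nrow(ns)))
      c1All <- c(c1All, rep(c1, nrow(ns)))
      bIdx <- c(bIdx, rep(b, nrow(ns)))
    }
  }
  list(lp = lpAll, seqIdx = seqIdx, c1 = c1All, bIdx = bIdx, ns = ns, B = B)
}
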