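# spikegrid

Spike-train inference from single-neuron calcium fluorescence recordings.

Calcium imaging reports action potentials only indirectly: each spike
raises intracellular calcium by a fixed amount, the bound indicator
fluoresces through a nonlinear response, the signal rides on a slowly
drifting baseline, and everything is buried in photon and system noise.
`spikegrid` recovers the spikes by inverting an explicit generative model
of this chain, for users who need actual spike times (temporal coding,
connectivity analysis) rather than smoothed activity estimates — and who
may have hundreds of neurons with cell-specific response amplitudes that
nobody can calibrate by hand.

## Model and algorithm

Normalized calcium decays exponentially and jumps by 1 per spike,

    c_t = c_{t-1} exp(-dt/tau) + n_t,      n_t ~ Poisson(lambda dt), capped

and the measured fluorescence is a drifting baseline times the probe
response, plus white noise:

    F_t = B_t (1 + A g(c_t)) + eps_t,      B_t = B_{t-1} + eta sqrt(dt) w_t

with `g` a normalized nonlinearity (`g(0)=0`, `g(1)=1`): dye saturation
`(1+gamma)c/(1+gamma c)` for synthetic dyes, a cubic polynomial or Hill
binding curve (optionally with finite rise time) for GECIs.

The maximum-a-posteriori spike train is computed by a Viterbi-style
backward recursion over a discretized (calcium, baseline) state space —
a histogram filter: off-grid children are evaluated by precomputed
spline-interpolation matrices along calcium and a locally refined
quadratic search along the baseline, so the recursion is a handful of
matrix products per frame and runs in linear time in the trace length.
The same machinery with sums instead of maxima returns per-bin spike
probabilities, or posterior-sampled spike trains.

A per-neuron **autocalibration** estimates the unitary amplitude `A`
(from the multimodal histogram of detected calcium-event amplitudes —
spikes are discrete, so isolated transient amplitudes cluster at the 1-,
2-, ... spike responses), the decay `tau` (least squares on isolated
transients) and the noise SD `sigma` (corrected 3–20 Hz band RMS),
directly from the fluorescence, with no ground truth required.

## Worked example

```r
library(spikegrid)

p   <- modelParams(A = 0.1, tau = 1, sigma = 0.02, lam = 0.5)
sim <- simulateTrace(spikeTrain(c(1, 2.2)), p, duration = 4, dt = 0.01,
                     seed = 2)
fit <- mapSpikes(sim$trace, p, spikeControl(nc = 60, nb = 30))
spikeTimes(fit)
#> [1] 0.995 2.195
evalSpikes(spikeTrain(c(1, 2.2)), fit)
#> EvalReport: ER=0.00% sens=1.000 prec=1.000 <|dt|>=5.0 ms r=1.000
```

Both simulated spikes are recovered in the correct 10 ms bins (times are
reported at bin midpoints, hence 0.995 for a spike at 1.0 s): zero error
rate at 0.5 s matching tolerance with a 5 ms mean timing error.

Autocalibration on three 30 s trials of a simulated neuron with unknown
amplitude and decay:

```r
prof   <- probeProfile("ogb")                       # saturating, gamma = 0.1
truth  <- modelParams(A = 0.051, tau = 0.67, probe = "saturating",
                      gamma = 0.1, lam = 0.3)
trains <- lapply(1:3, function(k) genBurstyTrain(0.3, 30, seed = 100 + k))
traces <- lapply(trains, function(tr)
  simulateTrace(tr, truth, 30, 0.01, noise = noiseSpec("white", 0.1),
                seed = nSpikes(tr))$trace)
autocalibrate(traces, prof)
#> CalibrationResult: A=4.9% tau=0.693 s sigma=0.0147/0.0159/0.017
```

The estimated amplitude (4.9% vs true 5.1%) and decay (0.69 s vs 0.67 s)
come from the event-amplitude histogram and isolated-transient fits; the
per-trial `sigma` is deliberately biased low by 0.7 for this dye profile
(it balances misses against false detections downstream).

A thin command-line front end (`inst/cli/spikegrid.R`) exposes
`simulate`, `infer` (map / proba / samples), `autocalibrate`, `evaluate`
and `benchmark` subcommands over the same functions, writing plain-text
spike lists, CSV paths and a JSON manifest that replays the run.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package: the pooled error
rate of MAP inference on the standard simulation benchmark (20 trials of
30 s at 100 Hz, spike rates 0.1–1 /s, A = 10%, tau = 1 s, flat baseline
unknown to the algorithm, white noise at 0.1–3 Hz band-RMS level 0.2),
and the amplitude and decay constant of the single exponential that best
fits the literature two-exponential OGB transient.  Results are written
as JSON to `--out`; all randomness derives from `--seed`.
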