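---
title: "Methods: grid-based MAP spike inference from calcium fluorescence"
author: "spikegrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-based MAP spike inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikegrid)
```

## The generative model

A neuron's fluorescence trace is modelled in three layers.

**Calcium.** The normalized intracellular calcium concentration $c$ is 0 at
rest and jumps by 1 for each action potential, relaxing exponentially with
time constant $\tau$.  Discretized at the frame interval $\Delta t$,

$$c_t = c_{t-1}\,e^{-\Delta t/\tau} + n_t,$$

where $n_t$ is the number of spikes falling in frame $t$'s bin.  Decay is
applied before the jump so that a single spike always produces a transient
of unit height in normalized units (amplitude $A$ in fluorescence).  Spike
counts per bin are capped at `nmax` (default 3).

**Probe.** The fluorescence response to calcium is a dimensionless
nonlinearity $g(c)$, normalized so $g(0)=0$ and $g(1)=1$ for every probe
type; the response to one spike from rest is therefore exactly $A$:

* *linear*: $g(c)=c$;
* *saturating* (synthetic dyes such as OGB): $g(c)=(1+\gamma)c/(1+\gamma
  c)$.  $\gamma$ is the inverse of the number of spikes at which the dye
  reaches half saturation; the asymptote is $(1+\gamma)/\gamma$ and half of
  it is reached at $c = 1/\gamma$;
* *polynomial* (phenomenological GECI supra-linearity):
  $g(c)=(1-p_2-p_3)c+p_2c^2+p_3c^3$, with $[p_2,p_3]=[0.73,-0.05]$
  (GCaMP6s) and $[0.55, 0.03]$ (GCaMP6f) as population-average values;
* *hill*: cooperative binding, $g(c)=(h(c)-h(0))/(h(1)-h(0))$ with
  $h(x)=(c_0+x)^n/\big((c_0+x)^n+(c_0+1/\gamma)^n\big)$; with $n=1$,
  $c_0=0$ this reduces identically to the saturating form;
* *hill_rise*: the same binding curve with a finite binding time constant
  $\tau_{on}$.  The bound-probe fraction $p$ becomes a third state
  variable, relaxing as $p' = p + (1-e^{-\Delta t/\tau_{on}})(g(c)-p)$.
  The exact exponential relaxation factor is used, so the update is stable
  for any $\Delta t/\tau_{on}$ and reduces to instantaneous binding at
  $\tau_{on}=0$.

GECI profiles add a fixed onset delay between a spike and the rise of its
transient (20 ms for GCaMP6s, 10 ms for GCaMP6f), implemented as a pure
time shift of the spike effect; estimated spike times are shifted back by
the same delay.

**Measurement.** The observed fluorescence is the product of a drifting
baseline with the calcium response, plus white noise:

$$F_t = B_t\,(1 + A\,g(c_t)) + \varepsilon_t,\qquad
  \varepsilon_t \sim N(0, \sigma^2),$$

in relative units where the resting baseline is about 1.  The baseline
follows a random walk of amplitude $\eta$ (units $\Delta F/F\,
s^{-1/2}$): $B_t = B_{t-1} + \eta\sqrt{\Delta t}\,w_t$.  We read the
"drifting baseline times nonlinear response" structure literally and apply
the drift additively in relative units (reflected at zero); whether the
original formulation drives the walk multiplicatively is not decidable
from the text, and the choice is isolated in one place of the simulator.

The free parameters are thus $A$, $\tau$, the probe parameters, $\sigma$,
$\eta$ and the a-priori spike rate $\lambda$.  The spike-count prior per
bin is Poisson($\lambda\Delta t$), truncated at `nmax` without
renormalization (the truncated mass is negligible for $\lambda\Delta t \ll
1$).

## MAP estimation on a discretized state grid

The estimator maximizes the posterior $p(x_1,\dots,x_T \mid y_1,\dots,y_T)$
over hidden-state paths $x_t = (c_t, B_t)$ (plus $p_t$ for `hill_rise`) by
a backward Viterbi-style recursion on the conditional best probability

$$m_t(x_t) = p(y_t \mid x_t)\,\max_{n,\,B_{t+1}}
  \big[\,p(n)\,p(B_{t+1}\mid B_t)\; m_{t+1}(x_{t+1})\,\big],$$

computed for every point of a discretization grid (default 100 calcium
values on $[0, 10]$ with square-root spacing — denser near rest, where
single spikes must be resolved — and 100 baseline values spanning
$\pm 30\%$ of an initial estimate, the 10th percentile of the trace).
Because calcium evolves deterministically given the spike count, only
`nmax + 1` candidate children exist per state; their (generally off-grid)
values of $m_{t+1}$ are obtained by natural cubic-spline interpolation
along calcium, precomputed once as one dense matrix per spike count so
each recursion step is a matrix product.  Along the baseline, a local
window (5 grid values centred on $B_t$) is searched and refined by fitting
a quadratic through the best value and its neighbours, maximized
analytically — the optimal next baseline need not lie on the grid.  All
recursions run in log space.

Initial priors on $c_1$ and $B_1$ are uniform over the grid (a resting
start, $c_1 = 0$, is available as an option and is used by the exactness
tests; a truncated-normal prior derived from a known spike rate is
deliberately not implemented as a default since a wrong rate degrades the
estimates).

A single forward collecting sweep then decodes the path: starting from the
argmax of $m_1$, the decisions at the running (off-grid) state are
re-derived by local cubic interpolation of the stored $m_t$ tables, ties
going to the lower spike count.  The reported log posterior is the exact
evaluation of the decoded path under the continuous model — not a grid
approximation — which is what makes bit-exact comparison against an
exhaustive-search oracle meaningful.

For `hill_rise`, the bound-probe fraction adds a companion dimension that
evolves deterministically, so it contributes an additional interpolation
(local cubic in $c$ times linear in $p$, stored sparse), not an additional
maximization.

### Spike probabilities and posterior samples

Replacing maxima by sums gives forward filtering $p(x_t\mid y_{1..t})$
(normalized per step) and backward conditional likelihoods $p(y_{t..T}\mid
x_t)$ on the same grid; pairing them across one transition yields the
posterior probability of each spike count in each bin.  The forward pass
pushes mass through the adjoint of the interpolation operator.  Two
numerical points matter:

* the spline adjoint carries small negative side lobes; they must **not**
  be clipped during filtering — clipping breaks the exact duality between
  mass pushforward and function interpolation and leaves a grid-resolution
  floor in the marginals (clamping is applied only to the final,
  normalized marginals);
* emissions are exponentiated after subtracting their per-frame maximum,
  and the subtracted constants accumulate into the log evidence.

With these in place the marginals converge at fourth order in the grid
spacing; at the test configuration (400 calcium values) they agree with an
exhaustive enumeration of all spike sequences to better than $10^{-6}$.

Posterior sampling draws $x_1$ from $p(x_1)\,p(y\mid x_1)$ and then
ancestrally from the transition prior reweighted by the backward
likelihoods, giving spike trains distributed per the same discrete-grid
posterior as the marginals — the Monte-Carlo agreement between the two is
a genuine consistency check, not a tautology, since the code paths share
only the backward tables.

## Autocalibration

Three parameters are estimated per neuron, the rest stay fixed
($\lambda = 0.1$/s; nonlinearity at the profile's population-average
values; $\eta$ at a fixed small default of 0.02 — the optimal value varies
little between cells and is not printed in the source material).

**Noise SD.** $\hat\sigma$ is the RMS of the trace band-passed 3–20 Hz
(below 3 Hz the calcium signal lives; the top of the spectrum is excluded
because real noise is not perfectly white), multiplied by a corrective
factor that makes the estimator exact on pure white noise.  The factor is
computed once per (frame rate, band) by a $2^{20}$-sample white-noise
Monte-Carlo and cached.  For OGB and GCaMP6f profiles the result is
multiplied by 0.7: deliberately underestimating $\sigma$ balances misses
against false detections.

**Calcium events.** The MAP engine is run with the spike-count
maximization replaced by a continuous event-amplitude maximization, with a
floor $A_{min}$ (4%): 12 log-spaced amplitude candidates between 4% and
50% $\Delta F/F$ with quadratic refinement across neighbouring candidates
in both passes.  The refinement is essential: without it the amplitude
quantization penalty (which scales as $1/\sigma^2$) makes the decoder
split clean transients into adjacent-bin fragments at low noise.
Detection runs with working values $A=10\%$, $\tau=0.8$ s, a linear
response (events are excluded above 25% anyway, where nonlinearity would
begin to matter) and a calcium range just covering the largest candidate
(`cmax = 6` working-amplitude units): a larger range admits a degenerate
decoding — baseline at the bottom of its grid with permanently elevated
calcium tracking the noise — that can overtake the honest decoding when
$\sigma$ is misspecified.

**Isolated events.** Detected jumps closer than 50 ms are first merged
into one calcium event with summed amplitude: at 100 Hz a spike burst
(10 ms inter-spike intervals) raises calcium across *adjacent frames* but
constitutes a single transient, and it is exactly these summed amplitudes
that populate the 2- and 3-spike peaks of the amplitude histogram — without
merging, the isolation rule below would discard every burst pairwise and
starve the histogram.  Events closer than 1 s to a neighbour or larger than
25% are then excluded; the predicted transients of the excluded events are
subtracted, and the kept events' amplitudes plus one shared $\tau$ are
re-fitted by least squares.  The subtraction uses the *same* $\tau$ the
fit is optimizing — subtracting with the fixed working $\tau$ leaves
systematic tails on slow-decay neurons that push the $\tau$ estimate to
its boundary.  Kept events whose re-fitted amplitude falls below
$A_{min}/2$ are removed as detection residue, and the fit repeated.

**Amplitude histogram.** Event amplitudes are histogrammed (40 bins over
$[0, 1.2\max]$), smoothed with a 1-bin Gaussian ($x_1$), peak-enhanced by
dividing by an 8-bin-smoothed copy ($x_2$), and scored as
$x_3(A)=x_2(A)+x_2(a_2(A))/2$ over $[A_{min}, A_{max}] = [4\%, 10\%]$,
where $a_2(A) = A\,g(2)$ is the two-spike amplitude under the probe
nonlinearity.  The kernel widths are not prescribed by the method's
description; the defaults resolve peaks separated by $A_{min}$ at
realistic event counts and are exposed as arguments.  Each event then
receives $k$ spikes with separations between $k$ and $k+1$ placed 30% of
the way from the $k$- to the $(k{+}1)$-spike amplitude (the classical
$(k+0.3)A$ rule for a linear probe); amplitudes below $0.3A$ drop out.
Final $A$ and $\tau$ come from a least-squares fit of the forward model
given the assigned counts, with the amplitude clamped to
$[A_{min}, A_{max}]$ and $\tau$ to $[0.1, 3]$ s — the use of a-priori
parameter ranges is a stated feature of this calibration philosophy.

When no usable isolated events exist the profile's default $A$ and $\tau$
are returned with a `fallback` flag and a warning; at band-RMS noise
levels above about 0.2 this becomes the norm, consistent with the known
operating range of the heuristic.

## Synthetic data

`genPoissonTrain` draws homogeneous Poisson trains.  `genBurstyTrain`
draws burst events as a Poisson process, a geometric (mean 1, zero
allowed) spike count per event, and Gaussian within-burst intervals of
mean 10 ms (SD 3 ms — not prescribed; negative draws resampled).

`genNoise` produces unit-variance series: white; pink, synthesized in the
frequency domain with $1/\sqrt f$ amplitudes, random phases and zero DC
(exact spectral control for the equal-power-per-octave property); and
"white plus drift", white noise plus a random walk low-passed below
0.1 Hz, mixed at equal total RMS (the mixture is not prescribed;
both the cutoff and the ratio are arguments).  The band-RMS **noise
level** of a series is its periodogram RMS inside 0.1–3 Hz divided by
$A$; `scaleNoiseToLevel` rescales against the *realized* periodogram, so
the definition holds exactly per trial, and the scaling is exactly
homogeneous in the level.

What the generator does *not* emulate: photon shot-noise statistics tied
to signal level (photonic noise is calibrated separately via the PMT gain
utilities), movement artifacts, neuropil contamination, photobleaching.
A green benchmark therefore establishes correctness of the inference
machinery under the model's own assumptions and the stated noise spectra,
not robustness to every real-data pathology.

## Evaluation

Spike trains are compared by a dynamic-programming minimum-cost alignment
with unit insertion/deletion cost and shift cost $2|\Delta t|/\mathrm{tol}$
(tolerance 0.5 s by default): the tolerance is thereby the exact
break-even matching radius, and no matched pair can be further apart.  The
error rate is $1 - F_1$ (one minus the harmonic mean of sensitivity and
precision, which biases towards the worse of the two); multi-trial
evaluations pool matched/missed/false counts before computing rates.  Rate
correlation bins true spikes at 40 ms and smooths estimated counts with a
100 ms Gaussian kernel; it is invariant to affine scaling of a rate
estimate, a documented shortcoming of that metric.  The residual noise
level of a recording divides the 0.1–3 Hz band RMS of (trace − predicted)
by the effective unitary amplitude $A' = A\,g(2)/2$ (or $A\,g(15)/15$ for
GCaMP5k), so that saturation lowers and supra-linearity raises the
denominator.

## Benchmarks, budgets and reproducibility

The standard benchmark (`runBenchmark`) simulates 30 s trials at 100 Hz
with Poisson rates swept over 0.1–1 sp/s, a flat baseline drawn uniformly
in $[0.85, 1.15]$ and *not* given to the algorithm, and noise scaled to a
band-RMS level; inference receives the generating parameters with
$\sigma$ set to the realized SD of the generated noise.  At level 0.2 the
pooled error rate stays below 1% and the 20-trial run takes well under a
minute; grid sizes of 30 reproduce the same pooled ER as 100.

Acceptance-test worlds are scaled to a CI budget: 200 twelve-bin oracle
instances (exhaustive enumeration bounded at $3^{11}$ sequences), 6-trial
benchmark variants, and 8–12 simulated neurons for the autocalibration
comparisons instead of larger populations; the seeds are fixed.  With 12
neurons the mean parameter-recovery error is dominated by a handful of
hard neurons (slow decay, few isolated events), and the strict
level-by-level monotonicity of the mean recovery error is at the edge of
what this sample size resolves; the per-level trend is reported by the
acceptance suite as measured.

All stochastic functions accept a `seed` and restore the RNG state on
exit; trial seeds inside the benchmark derive linearly from the base seed
and stay within 32-bit integer range for any seed below $2^{21}$.

## Known limitations

* When $\sigma$ is badly misspecified the MAP decoder can favour
  degenerate explanations (baseline at a grid edge compensated by
  calcium); the event-detection configuration avoids this by bounding the
  calcium range, but ordinary inference with a grossly wrong $\sigma$
  inherits the risk.
* The truncated-normal initial-calcium prior for a known spiking rate is
  not implemented; the resting-start option covers the cases where the
  initial state is genuinely known.
* Posterior sampling is restricted to probes without the bound-probe
  dimension (`hill_rise` supports MAP decoding only).
* Autocalibration quality degrades above noise level ~0.2 and at high
  spike densities, where isolated events become rare — the method then
  falls back to profile defaults rather than extrapolating.
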