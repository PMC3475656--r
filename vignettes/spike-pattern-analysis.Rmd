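---
title: "Spike-time patterns, events and bifurcation points"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-time patterns, events and bifurcation points}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When the same fluctuating ("frozen noise") current is injected into a
cortical neuron on many trials, the spike times repeat with millisecond
precision — but not always as a single stereotyped sequence. At particular
stimulus amplitudes or offsets the ensemble splits into two or more
*spike patterns*: distinct sequences of *events* (temporally localized
concentrations of spike-time density across trials). These parameter values
behave like bifurcation points of the membrane-potential dynamics: a small
change in drive reorganises the spike sequence, so trial-to-trial noise is
enough to realise several coexisting patterns at once. Operationally this
shows up as a dip in the trial-to-trial reliability exactly where the mean
spike count steps between plateaus.

`spikepatterns` implements the full computational side of this programme:

1. stimulus synthesis (frozen noise, scaled currents, FM drives);
2. stochastic simulation of the Wang–Buzsáki (WB) model neuron;
3. spike-train metrics (Schreiber R-reliability, Victor–Purpura distance,
   PSTH, firing rate, spike-triggered average);
4. the unsupervised event-finding pipeline (fuzzy c-means pattern
   clustering on the VP distance matrix, interval-method event detection,
   ROC-based merging of events shared between patterns);
5. entropy and mutual information of pattern distributions, with
   resampling bias estimates;
6. event-based stimulus reconstruction; and
7. amplitude/offset sweeps with bifurcation-candidate flagging.

A synthetic ensemble generator with known ground truth
(`generate_pattern_ensemble()`) makes every analysis stage testable without
the simulator.

## The stimulus

The frozen-noise template `h(t)` is uniform white noise at 10 kHz passed
through two causal filters — the first-order recursion
`y[n] = x[n] + 0.99 y[n-1]` (about a 100 Hz corner) and a 5 ms running
average — after which the first 50 ms are discarded and the remainder is
standardised to zero mean and unit *population* variance (the vector is a
long deterministic object, so the population convention is the natural
reading of "unit variance"). Both filters run as direct-form recursions
with zero initial state. The injected current is

\[ I(t) = \nu\,(a + b\,h(t)) \]

with relative offset `a`, relative amplitude `b` and an overall gain `nu`
that maps the dimensionless template onto µA/cm² of model drive. Exact
reproduction of the original MATLAB random stream is not attempted; any
seed gives a valid template and the seed is recorded with the condition.

For reconstruction experiments a frequency-modulated sinusoid
(`generate_fm_waveform()`) replaces the Gaussian-process-like template: a
chain of upswings of identical peak height arriving at variable intervals
and slopes, so the stimulus "features" a spike can report are unambiguous.
The default segment table (`fm_default_segments()`) walks irregularly
through 5–25 Hz, giving roughly 15 upswings in 1100 ms.

## The model neuron

The WB neuron is a single compartment with fast sodium (activation slaved
to `m_inf(V)`), delayed-rectifier potassium and leak currents:

\[ C_m \dot V = -g_L(V{-}E_L) - g_{Na} m_\infty^3 h (V{-}E_{Na})
   - g_K n^4 (V{-}E_K) - g_{slow}\,z\,(V{-}E_K) + I_{inj} + \xi \]

with Table-standard parameters `E_L = -65`, `E_Na = 55`, `E_K = -90` mV,
`g_L = 0.1`, `g_Na = 35`, `g_K = 9` mS/cm², `C_m = 1` µF/cm², and gate
kinetics accelerated by the dimensionless factor `zeta = 5`. The optional
slow potassium current is gated by `z`, which charges toward 1 with a 10 ms
time constant whenever `V` exceeds `V_z` (default −20 mV, i.e. only during
the action-potential upstroke — the supplement leaves the switching voltage
open, and −20 mV makes the gate a pure spike counter; sensitivity to this
choice is mild because the spike upstroke traverses the whole plausible
range in a fraction of a millisecond) and decays toward 0 with a 500 ms
time constant otherwise.

Integration is second-order Runge–Kutta (midpoint) at `dt = 0.05` ms. The
intrinsic noise current has autocorrelation `2λ δ(t−t′)`: each step draws
one uniform variate, holds it through both RK stages, and uses bounds
`±sqrt(6λ/dt)` so that the discrete variance is exactly `2λ/dt`
(`noise_dialect = "contract"`). A `"literal"` dialect with bounds `±12λ/dt`
is kept for comparison with a historical convention that is dimensionally
inconsistent with the autocorrelation contract; the contract dialect is the
default because the autocorrelation is the operative definition. Gates
start at `x_inf(V0)` with `V0 = -70` mV. Spike times are the first sample
at which `V` reaches 0 mV from below; no sub-sample interpolation is
applied. At `dt = 0.05` ms the RK2 tonic-firing period retains a residual
discretisation error of about 1% relative to a tenfold-refined run — the
cost of honouring the conventional step size.

## Trial-to-trial metrics

The R-reliability convolves each train with a Gaussian of SD `sigma` and
averages the cosine similarity over all trial pairs. The cosine is
evaluated analytically through the Gaussian product identity (the inner
product of two unit Gaussians at `t_k`, `t_l` is proportional to
`exp(-(t_k-t_l)^2/4σ^2)`), skipping pairs further apart than `6σ`; the
worst-case effect of the cutoff is one kernel value, `exp(-9) ≈ 1.2e-4`.
Empty trains are assigned similarity 0 — silent trials are maximally
unreliable, and leaving them out would inflate R. `sigma = 3` ms is the
convention for slice data; `sigma = 1` ms resolves the faster, more
precise model spiking in the sweeps.

The Victor–Purpura distance uses the standard dynamic program with
insert/delete cost 1 and shift cost `q` per ms. `q = 0.5` is the package
default for clustering: moving a spike 2 ms then costs as much as deleting
it, matching the few-ms event scale set by `t_ISI = 3` ms.

## The event-finding pipeline

Analysis proceeds per segment of roughly 500 ms holding two to six events;
`segment_trials()` cuts at sub-threshold local minima of the smoothed PSTH
near the nominal boundaries, falling back to fixed-length cuts. Spikes are
assigned to segments by half-open windows `[start, end)`.

Within a segment:

1. **Distance matrix.** Pairwise VP distances between trials.
2. **Cluster count.** `select_n_clusters()` embeds the trials by classical
   MDS of the distance matrix (4 dimensions by default) and compares the
   FCM clustering's *size-weighted* within-cluster dispersion
   `W(k) = Σ_r D_r / (n_r(n_r−1))` against 20 reference draws from the
   uniform bounding box, on the log scale. The plain gap statistic is
   unusable on distance-profile features: the box reference is nearly
   unclusterable there, so the gap rises monotonically and the one-SE rule
   saturates at `k_max`. The weighted dispersion (insensitive to peeling
   off small sub-clusters, which spike unreliability creates inside every
   true pattern) plus a two-part rule — the one-SE stop restricted to
   non-negative gaps, else the gap-curve elbow (maximal second difference)
   — recovers designed cluster counts from one to four reliably in
   simulation. A negative gap is excluded as a stopping point because it
   marks a partition that fits worse than structureless data, the
   signature of a poor intermediate-k solution below the true count.
3. **Pattern clustering.** Fuzzy c-means (`e1071::cmeans`, fuzzifier 2,
   up to 1000 iterations) on the columns of the distance matrix, best of
   10 seeded restarts by objective; hard labels by maximal membership,
   ties to the lowest index.
4. **Events per pattern.** The interval method on each pattern's aggregate
   spike train: a new event starts where the gap between consecutive
   aggregate spikes exceeds `t_ISI = 3` ms (a gap exactly equal does not
   split).
5. **Merging shared events.** Events from different patterns whose time
   supports overlap are compared by Mann–Whitney AUC; discriminability
   `d = 2|AUC−0.5| ≤ t_ROC = 0.5` merges them (transitively, via
   union-find). Events sharing a contributing pattern are never merged,
   which also makes the operation idempotent.
6. **Noise rule.** Events represented in fewer than two distinct trials
   are reclassified as noise (the analysis needs population events; the
   original description acknowledges noise spikes without fixing a rule).

Event reliability is the fraction of trials contributing at least one
spike, jitter the sample SD of the event's spike times, precision
1/jitter; single-spike events report jitter 0, precision missing, and are
excluded from condition-level averages. Firing-rate SDs across trials also
use the sample (n−1) convention.

## Information measures

Pattern labels form a classification of the trials; diversity is the
plug-in entropy in bits with `0 log 0 = 0`. Bias and spread of the
estimate come from 1000 multinomial resamples at the observed trial count
(the plug-in estimator is biased downward; no bias correction is applied —
bias is reported alongside, mirroring the reporting style of the
experimental literature). Association between two classifications (e.g.
patterns in different segments) is the plug-in mutual information,
normalized by `max(S(c), S(d))` — the unique normalisation that equals 1
exactly for identical classifications; normalising by `log2 N_c` would
break that identity. Two zero-entropy classifications trivially determine
each other, so their normalized MI is defined as 1 (this also preserves
relabelling invariance).

## Event-based reconstruction

Each detected event with reliability above 5% contributes one equally
weighted copy of the spike-triggered average (the mean 25 ms of stimulus
preceding a spike), anchored with its lag-0 point at the event's mean time
so that every event paints the stimulus history that produced it.
Overlapping contributions sum (a maximum rule was considered and rejected:
summation keeps the operation linear in the event set, which is also the
tested invariant), and the result is z-scored. Each noise condition uses
its own measured STA. Reconstruction quality is the Pearson correlation
with the true waveform over the common support.

## Sweeps and bifurcation candidates

`scan_amplitude()` / `scan_offset()` simulate an ensemble per condition and
record the R-reliability plus the spike-count mean and SD across trials.
Per-trial seeds derive deterministically from `(base_seed, condition,
trial)`, so any condition reproduces in isolation. The reliability curve is
also reported as a 3-point running average with shrink-to-window endpoints.
Bifurcation candidates are interior local minima of the reliability curve,
at least 0.02 deep relative to their flanking maxima, lying within one
condition step of a change in rounded mean spike count. Detection defaults
to the *raw* curve: on the scaled-down grids used here (21 conditions) the
3-point average demonstrably erases dips it would merely soften on a
101-condition grid; the smoothed curve remains available via `curve =
"smooth"`.

Problem sizes are deliberately scaled down from the full study design
(101 amplitudes × 50 trials) to 21 × 25 for routine runs — the package's
default experiment, chosen to keep a sweep in seconds while preserving the
peak/plateau/dip structure; the full design is one argument away.

## The synthetic generator and what passing tests mean

`generate_pattern_ensemble()` draws, per trial, a pattern by its occupation
probability, realises each of the pattern's events with its reliability and
Gaussian jitter, and adds homogeneous-Poisson contaminant spikes. It
emulates exactly the statistical structure the analysis assumes — and
nothing more. It does *not* emulate afterhyperpolarisation-induced
correlations between successive events (that is the simulator's job),
non-stationarity across trials, or bursting. Ground-truth recovery on these
ensembles therefore validates the pipeline's statistical machinery; the WB
simulations validate the dynamical claims (dips at count transitions,
pattern multiplication under noise, slow-current pattern memory).

The standard recovery condition used in the tests — three patterns of three
events each, jitter 1 ms, reliability 0.9, inter-event gaps ≥ 20 ms, 60
trials — is scored on the cluster count, the event count, the mean absolute
error of event means (≤ 0.5 ms) and the mean event reliability (within
0.05). Means are compared in aggregate because the per-event estimator SE
at this design (jitter/√n ≈ 0.24 ms; binomial SE ≈ 0.067) makes per-event
bounds at those tolerances unattainable even for an ideal estimator.

## The reconstruction experiment's operating point

The FM comparison runs the WB neuron at amplitude 0.4 µA/cm² and offset
0.05 µA/cm², an operating point chosen once so that the low-noise neuron
(`λ = 1e-4` mV²/ms) spikes at a strict subset (about a third) of the
upswings — i.e. near a bifurcation, where the medium-noise condition
(`λ = 0.025` mV²/ms) can recruit additional, less reliable events. With 100
trials per condition the event-based reconstruction from the medium-noise
ensemble correlates better with the drive than the low-noise one, the
package's analogue of the published comparison.

## Known limitations

* The slow-gate switching voltage and the exact cluster-count heuristic of
  the original method are under-specified in the sources; both are
  implemented as documented package choices and may differ in edge cases.
* Spike times are not interpolated below the integration step.
* The FCM feature space (distance-matrix columns) makes cluster geometry
  depend on ensemble size; the MDS embedding in `select_n_clusters()`
  mitigates but does not remove this.
* Single-process execution only; the full 101 × 50 sweep takes minutes,
  not hours, but is not parallelised.
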