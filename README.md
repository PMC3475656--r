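# spikepatterns

Tools for analysing how neurons driven repeatedly by the same fluctuating
("frozen noise") current organise their spike times into **events** and
**patterns**, and for locating the **bifurcation points** — stimulus
amplitudes or offsets at which the spike sequence reorganises, multiple
patterns coexist, and trial-to-trial reliability dips.

The package is aimed at computational and systems neuroscientists working
with repeated-trial spike data (slice current-injection experiments or
conductance-based simulations). It provides:

* **Stimulus synthesis** — the doubly low-pass-filtered frozen-noise
  template *h(t)*, scaled currents *I(t) = ν(a + b·h(t))*, and
  frequency-modulated drives with phase-continuous segments.
* **Model neuron** — the Wang–Buzsáki single-compartment neuron (fast Na⁺
  with instantaneous activation, delayed-rectifier K⁺, leak, optional slow
  K⁺ current), integrated by second-order Runge–Kutta at 0.05 ms with
  per-trial white-noise current of variance 2λ/dt per step (Rcpp core).
* **Metrics** — Schreiber R-reliability (mean pairwise cosine similarity
  of Gaussian-smoothed trains, computed analytically), the Victor–Purpura
  edit distance *d(q)* (insert/delete cost 1, shift cost *q*·|Δt|), PSTH,
  trial-averaged firing rates, spike-triggered averages.
* **Event finding** — fuzzy c-means clustering of trials into patterns on
  the columns of the VP distance matrix, a weighted-gap-statistic choice of
  the cluster count, interval-method event detection per pattern
  (*t*<sub>ISI</sub> = 3 ms), and ROC-based merging of events shared
  between patterns (*t*<sub>ROC</sub> = 0.5).
* **Information measures** — entropy of pattern distributions (bits) with
  multinomial-resampling bias and spread, mutual information between
  classifications, and normalized MI `I_N = I / max(S_c, S_d)`.
* **Reconstruction** — event-based stimulus reconstruction in which every
  event above 5% reliability paints one copy of the spike-triggered
  average before its mean time.
* **Sweeps** — amplitude/offset scans that pair the reliability curve with
  spike-count plateaus and flag dip/count-step coincidences as bifurcation
  candidates.
* **Synthetic ground truth** — a generator of spike-train ensembles with
  designed event times, jitters, reliabilities and pattern occupations, so
  the whole pipeline can be validated without a simulator.

Everything takes and returns tibbles, pipes cleanly, and has
`autoplot()`/`tidy()`/`glance()` methods.

## Worked example

Two spike patterns share no events; each trial expresses one of them.
The pipeline recovers the patterns, the six events and their statistics:

```r
library(spikepatterns)

specs <- list(
  pattern_spec(c(50, 120, 200), reliabilities = 0.9, jitters = 1,
               occupation = 0.5),
  pattern_spec(c(80, 150, 230), reliabilities = 0.9, jitters = 1,
               occupation = 0.5)
)
ens <- generate_pattern_ensemble(specs, n_trials = 60, duration_ms = 300,
                                 seed = 42)
pa <- find_spike_patterns(ens, q = 0.5, t_isi = 3, t_roc = 0.5, seed = 1)
pa
#> <pattern_analysis: 2 patterns, 6 events>
#> # A tibble: 6 × 10
#>   event mean_time t_min t_max n_spikes n_trials_hit reliability jitter precision
#>   <int>     <dbl> <dbl> <dbl>    <int>        <int>       <dbl>  <dbl>     <dbl>
#> 1     1      50.0  48.8  52.7       31           31       0.517  0.908     1.10
#> 2     2      80.3  77.9  81.8       23           23       0.383  1.02      0.980
#> 3     3     120.  118.  122.        30           30       0.5    0.811     1.23
#> 4     4     150.  148.  152.        22           22       0.367  1.16      0.858
#> 5     5     200.  198.  202.        32           32       0.533  1.06      0.947
#> 6     6     230.  228.  232.        23           23       0.383  1.15      0.872
```

The six events sit at the designed times (50, 80, 120, 150, 200, 230 ms)
with jitter near the designed 1 ms. Each event's `reliability` is relative
to all 60 trials, so an event of a pattern occupying about half the trials
with 90% within-pattern reliability reads ≈ 0.45.

```r
glance(r_reliability(ens, sigma = 3))
#> # A tibble: 1 × 3
#>       R sigma n_pairs
#>   <dbl> <dbl>   <int>
#> 1 0.424     3    1770
```

R ≈ 0.42: roughly half the trial pairs share a pattern (similarity near 1),
half do not (similarity near 0) — reliability conflates pattern multiplicity
with spike-time precision, which is exactly why the event-based analysis
exists.

```r
pattern_occupation(pa$assignment)
#> # A tibble: 2 × 3
#>   label     n occupation
#>   <int> <int>      <dbl>
#> 1     1    25      0.417
#> 2     2    35      0.583

entropy_resample(class_distribution(pa$assignment$label, pa$n_c),
                 n_trials(ens), seed = 1)
#> # A tibble: 1 × 3
#>   entropy    bias    std
#>     <dbl>   <dbl>  <dbl>
#> 1   0.980 -0.0119 0.0341
```

The pattern distribution carries 0.98 bits (close to the 1-bit maximum of a
50/50 mix); the resampled bias of the plug-in entropy is about −0.01 bits.

For a model-neuron experiment, sweep the stimulus amplitude and look for
reliability dips at spike-count transitions:

```r
h  <- generate_frozen_noise(seed = 0, n_keep = 10500)   # 1050 ms at 10 kHz
sc <- scan_amplitude(wb_params(), h,
                     amplitudes = seq(0, 1, length.out = 21),
                     a = 0.2, n_trials = 25, lam = 0.00025, sigma = 1,
                     base_seed = 1)
attr(sc, "candidates")      # conditions where a dip meets a count step
autoplot(sc)
```

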