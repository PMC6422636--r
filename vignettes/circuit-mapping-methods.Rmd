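---
title: "Methods: statistical inference for SST circuit mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical inference for SST circuit mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitmap)
```

# Scope

`circuitmap` implements the statistical machinery used to infer the wiring of
cortical somatostatin (SST) interneuron subnetworks from four kinds of
electrophysiology data: optogenetic photostimulation maps recorded as
IPSC/EPSC event trains, simultaneous pair recordings probed for fine-timescale
common input, paired-recording connectivity tallies, and in vivo unit
recordings under optogenetic perturbation. Because no raw recordings of this
kind are publicly deposited, every stage is validated against a synthetic-data
generator that produces data with the same statistical structure from known
ground-truth circuits; a green test therefore establishes that the machinery
recovers what it is supposed to recover *under the stated generative
assumptions*, not that any particular biological claim is reproduced.

# Evoked-input detection from event trains

A mapping session stimulates one grid site per trial (default 20 µm spacing
over 400 × 400 µm, i.e. 400 sites; 100 ms inter-trial interval). For each
recorded cell:

1. **Background rate** is estimated from the last 25 ms of every inter-trial
   interval: total events over total time (`background_rate`).
2. **Per-site evoked counts** are taken in a half-open window
   [onset + 5 ms, onset + 35 ms); events at a boundary belong to the later
   interval. The 5 ms offset reflects the latency floor of optogenetically
   evoked spikes; the 30 ms width covers their observed spread.
3. **Poisson test**: the p-value is the upper tail P(X ≥ observed) under
   X ~ Poisson(background × window × trials) (`site_pvalue`). An observed
   count of zero always gives p = 1. If a cell's background estimate is
   exactly zero while events were observed, the rate is floored at one
   pseudo-event over the total background-estimation time so p never
   degenerates to 0.
4. **FDR control**: Benjamini–Hochberg at q = 0.1 across the grid sites of
   each recorded cell (`detect_input_sites`). The level is deliberately
   liberal because the synchrony stage below re-tests candidate sites.

# Fine-timescale common-input testing

When two simultaneously recorded cells both receive input at a site, the
events may come from one presynaptic cell diverging onto both, or from two
neighbouring cells co-activated by the same stimulus. The discriminating
signal is millisecond-scale synchrony: a diverging axon produces IPSCs whose
*within-trial, across-cell* timing is much tighter than the *across-trial*
latency jitter of evoked spiking.

* Events are binned per trial at 1 ms (half-open bins, multiple events per
  bin collapse to one).
* The synchrony statistic is the sum of the centre and two flanking bins of
  the cross-correlation of the binary trains, accumulated over trials — the
  number of occupied-bin pairs within ±1 ms (`synchrony_statistic`).
* The null preserves all structure coarser than δ = 10 ms by interval
  jitter: each trial's axis is partitioned into fixed contiguous δ windows
  anchored at stimulus onset, and every event is re-placed uniformly within
  its own window, independently per event, trial and cell (`jitter_null`).
  Per-window counts are conserved by construction, so trial-to-trial
  co-activation survives while fine synchrony is destroyed. The resampler is
  implemented in C++ with an R reference implementation cross-checked in the
  test suite.
* p = (1 + #{null ≥ observed}) / (1 + resamples), with 1999 resamples by
  default so the smallest attainable p is 0.0005.
* Candidate-site p-values are pooled across all pairs and BH-controlled at
  q = 0.05 (`detect_common_inputs`); the per-pair common-input probability is
  |common sites| / |union of input sites| (`pair_summary`).

Two variants the literature leaves open: jitter may be applied to both trains
(symmetric null, default) or only one; and the δ-partition phase is anchored
at stimulus onset — the suite checks that detection of a genuinely shared
source survives a δ/2 phase shift.

# Hierarchical connection-rate comparison

Paired-recording datasets are hierarchical: several connections are tested on
the same presynaptic cell, so connections are not independent. The package
treats *cells* as the exchangeable units. `permutation_test` reassigns the
pooled cells (each with its own tested-connection outcomes) randomly between
the two groups, preserving each group's cell count, and builds the null
distribution of rate differences; on flat data (one connection per cell) this
reduces exactly to the classical two-sample permutation test, which the suite
verifies against a hypergeometric oracle. The test is one-tailed with an
a-priori direction; choosing the tail after seeing the data is available as
`alternative = "observed"` but roughly doubles the type-I error.

A literal "resample cells with replacement, then resample each placed cell's
outcomes to the target cell's connection count" scheme is provided as
`method = "bootstrap"`. Measured on null datasets, its null distribution is
~1.65× wider than the true sampling distribution (within-cell noise is drawn
on top of between-cell variation that already contains it), making the test
strongly conservative; it is retained for comparability, not as the default.
When a bootstrap-placed cell has fewer tested connections than its slot,
outcomes are drawn with replacement — implemented as a Binomial draw at the
cell's empirical rate, which is distributionally identical and fast.

# Intrinsic electrophysiology

* **Spike onsets** are found in the phase space of V and dV/dt: within each
  segment flagged by a 20 mV/ms dV/dt pre-detector, the onset is the point of
  maximum d(dV/dt)/dV along the trajectory. Derivatives are central
  differences on a 3-sample boxcar-smoothed copy, and the phase-space slope
  is evaluated only across voltage increments > 0.25 mV — below that the
  ratio is dominated by discretization noise on nearly flat trajectory
  segments. The pre-detector threshold sits above passive charging slopes
  (≤ ~13 mV/ms for realistic R~in~ and step sizes) and far below any spike
  upstroke.
* **Spike width** is the full width at the voltage halfway between threshold
  and peak, with linear interpolation between samples.
* **Adaptation index** is the mean normalized successive-ISI contrast,
  (1/(m−1)) Σ (ISI~n+1~ − ISI~n~)/(ISI~n+1~ + ISI~n~). The printed form of
  this formula indexes one more ISI than exists for N spikes; the reading
  adopted here (m = N − 1 ISIs, m − 1 summands) is the one that makes the
  sum well-posed and matches the widely used cell-typing protocol it cites.
  It requires ≥ 3 spikes and returns a flagged missing value otherwise.
* **Rheobase** is the average of (1) the zero-rate crossing of a
  nonnegative-coefficient linear fit to the F-I relation over the last
  subthreshold step and the first k = 3 suprathreshold steps and (2) Ohm's
  law, (mean threshold − V~rest~)/R~in~. The nonnegativity constraint is
  applied to the design (slope, −intercept), i.e. slope ≥ 0 and a
  non-negative zero-crossing — the only parameterization under which a
  constrained fit can cross zero at positive current. "First few" is read as
  k = 3 and is configurable.
* **Subtype classification** uses a maximum-margin linear classifier on
  standardized (spike width, rheobase); no SVM library is available in the
  target environment, so a compact full-batch subgradient solver for the
  L2-regularized hinge loss is included. Regularization is fixed (λ = 0.01,
  standardized inputs); accuracy is reported from stratified 10-fold
  cross-validation and never tuned on test folds.

# In vivo analysis

Units pass inclusion when at most 3% of inter-spike intervals violate a 2 ms
refractory period (burst-firing units may be kept via an explicit override —
no automated criterion is offered because none is defined). Units are classed
fast-spiking below 0.36 ms trough-to-peak latency, regular-spiking above
0.38 ms, excluded between. Analysis trials require running ≥ 1 cm/s within
1.5 SD of the animal's mean speed; with zero speed variance the deviation is
zero and trials are kept. Firing rates count spikes in a half-open 750 ms
window starting 500 ms after motor onset (the LED period on light trials).

The modulation test is a Poisson regression of per-trial window counts on the
light indicator with the window as exposure. The reported p-value is the
likelihood-ratio test of the light coefficient; an F-test on the
quasi-Poisson fit is available as `method = "ftest"`. The likelihood-ratio
test is primary because an F-test on a single-coefficient Poisson model is
not uniquely defined without a dispersion model; both calibrate correctly on
simulated null units.

PSTHs are trial-averaged at 1 ms, smoothed with a causal alpha kernel
α(t) = (t/τ²)e^(−t/τ) (τ = 100 ms, discretized to unit integral so constant
rates are conserved), block-averaged to 50 Hz, and z-scored against the
pre-motor second of each trial ([−1, 0) s relative to motor onset — the
baseline window is a package choice, as only z-scored traces are shown in the
source material).

# The synthetic world

The generator's defaults state one fixed world; none of them are tuned to
test outcomes:

* **Stimulation**: 20 µm grid over 400 × 400 µm (400 sites), 10 ms pulses,
  100 ms ITI, 10 trials per site.
* **Photoexcitation**: spike probability falls off as a Gaussian of radial
  distance with 15 µm half-width (the source reports high radial resolution
  but no functional form) and 0.95 at the soma. Evoked spike latency is
  Gamma(mean 8 ms, SD 3.5 ms) truncated at 20 ms: most evoked spikes within
  20 ms, almost none before ~4 ms — chosen for internal consistency with the
  5 ms analysis-window offset, which exists precisely because evoked spikes
  almost never arrive earlier.
* **Synapses**: latency 1.5 ms, Gaussian jitter SD 0.3 ms (delay floored at
  0.1 ms), release failure 0.1. Divergence is exclusive (each SST cell
  targets L4 or L5 PCs, never both) or mixed with a stated fraction.
* **SST density**: 12 cells per 400 × 400 µm field, matching the sparse
  labeling visible in soma-targeted opsin experiments; the source states no
  density, so this is a free parameter of the world, not a claim.
* **Background IPSCs**: homogeneous Poisson, 5 Hz per cell.
* **Spiking neuron**: a steady-state threshold model. Subthreshold steps
  settle to V~rest~ + I·R~in~; suprathreshold steps emit stereotyped
  triangular spikes on a linear F-I schedule (base ISI = 1000/(gain·(I −
  rheobase)), gain 0.3 Hz/pA), with geometric ISI adaptation ISI~n+1~ =
  ISI~n~(1+a)/(1−a) that saturates after 5 intervals. The geometric rule
  makes each adapting successive-ISI contrast equal exactly `a` (clean
  ground truth); the saturation reflects that spike-frequency adaptation in
  cortical neurons accumulates over the first few ISIs of a step rather than
  compounding indefinitely — an ever-growing ISI would collapse firing
  within a 1 s step and make the spike-count F-I so concave that no
  F-I-based rheobase estimator could work on any data, contradicting the
  model's purpose as a feature-recovery test bed. This is deliberately not a
  conductance model: it exists to give the feature extractors exact known
  answers.
* **In vivo units**: Poisson spiking at a base rate, multiplied by the
  light effect inside the analysis window of light trials; trough-to-peak
  latencies from a bimodal mixture straddling the 0.36/0.38 ms boundary;
  running speeds Normal(41, 25) cm/s floored at zero.

What the generator does **not** emulate: overlapping photostimulation of
multiple cells with partial efficacy gradients, non-stationary background
rates, electrotonic filtering differences across synapse locations, true
conductance-based spike shapes, bursting, or sorted-unit contamination.
Green tests say nothing about those.

# Numerical and degenerate-case choices

* Event tables are sorted within (cell, trial) and deduplicated at sample
  resolution on every generator output.
* The trace detrender subtracts a down-sampled (factor 100) and
  median-filtered (200 ms) version of the recording; both are configuration
  keys since the source states neither. Charge is a trapezoidal integral
  over stimulation plus 25 ms, with a polarity convention selected by the
  caller so reported charge from a genuine response is non-negative.
* The stand-in event detector is a matched filter (bi-exponential template,
  robust MAD noise scale) with greedy shoulder-subtracting peak acceptance
  and a 2 ms minimum separation; two events 1 ms apart merge into one. All
  downstream statistics consume event times only, so swapping in a
  posterior-sampling detector changes nothing structurally.
* Charge-map binarization draws surrogate evoked charges from the baseline
  samples so that a site exceeding every baseline value attains the minimal
  p of 1/(n~perm~ + 1), with Bonferroni correction per map (whether the
  original correction counted sites per map or per dataset is not stated;
  per-map is implemented).
* Map alignment estimates rotation by a least-squares line fit to annotated
  L4–L5 boundary points, rotates about the map centre with bilinear
  interpolation, aligns boundaries at depth 0, registers horizontally on the
  home column or soma, crops to ±300 µm and averages over overlapping
  support. Alignment is idempotent up to the interpolation support at map
  edges.
* Monte Carlo p-values always carry the +1 correction and can never be 0.

# Known limitations

* The F-I rheobase estimator inherits a small negative bias from the 50 pA
  step granularity (the fitted zero crossing falls between the last
  subthreshold step and the true rheobase); averaging with the Ohm's-law
  estimator keeps the mean absolute error across the tested parameter grid
  under 10%, but individual low-rheobase cells can err by more.
* The cell-permutation null assumes cells are exchangeable between groups
  under the null — heterogeneity in connections-per-cell between groups is
  preserved only marginally.
* The synchrony test's power depends on the ratio of across-trial latency
  jitter to within-trial synaptic jitter; for sources with unusually
  reliable latencies the interval-jitter null loses power rather than
  inflating false positives.
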