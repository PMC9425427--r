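---
title: "Methods: optogenetic circuit-mapping analysis in cracm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optogenetic circuit-mapping analysis in cracm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cracm)
```

# The analysis problem

Channelrhodopsin-assisted circuit mapping (CRACM) asks whether an
optogenetically defined presynaptic population makes functional synapses onto
a recorded neuron, and whether those synapses matter for the neuron's output.
In the striatonigrostriatal setting this package targets, GABAergic neurons
of the substantia nigra pars reticulata (SNr) express ChR2 and the recorded
cells are projection-defined dopamine neurons of the pars compacta (SNc).
Three assays are analyzed:

1. **Monosynaptic connectivity.** Whole-cell voltage clamp at -70 mV with a
   high-chloride internal (inhibitory currents appear inward), TTX + 4-AP to
   isolate monosynaptic, terminal-driven release, and NBQX + D-AP5 to block
   glutamatergic currents. A 5 ms light pulse is delivered in 5-10 sweeps at
   30 s intervals; the question per cell is whether a light-evoked IPSC
   (oIPSC) is reliably present.
2. **Suppression of tonic firing.** Loose-seal (20-100 MOhm) recordings of
   the cell's pacemaker spiking, with a 3 s, 20 Hz light train; the question
   is whether the train reduces the firing rate beyond its baseline
   variability.
3. **Short-term plasticity.** Whole-cell at -40 mV with a low-chloride
   internal (oIPSCs appear outward) under the same 20 Hz / 3 s train; per
   pulse amplitudes, the paired-pulse ratio (PPR, second/first) and the
   last/first ratio describe release dynamics over the train.

All currents are in pA, times in ms, voltages in mV, resistances in MOhm;
inward current is negative; each sweep starts at t = 0 with sweep-relative
light onsets. Cohort tables convert amplitudes to nA.

# Event detection (whole-cell)

An oIPSC is defined operationally as a *fast-onset* event: a monotonic
excursion of the current in the configured polarity sustained for a fixed
window, beginning shortly after the light pulse. Two presets encode the two
assays:

* `preset_minus70()`: inward polarity, 1.5 ms monotonic window, onset within
  20 ms of the light pulse.
* `preset_minus40()`: outward polarity, 0.5 ms monotonic window, onset within
  5 ms of the light pulse.

Strict sample-wise monotonicity is meaningless at 10 kHz in the presence of
noise, so `detect_oipsc()` evaluates the run on a lightly smoothed trace
(0.3 ms moving average) with tolerances scaled to the noise of the quantity
each test thresholds:

* per-sample counter-steps are tolerated up to 2.5x the SD of one smoothed
  step (`noise * sqrt(2) / k` for a k-sample moving average);
* the first step of the run must itself move in the event direction by at
  least 1.5x that SD — without this, runs starting in pre-onset noise whose
  tail catches a large event would anchor the onset early and bias latencies;
* the net excursion over the run, and over its first third, must clear 3x and
  2x its own noise SD respectively and be strictly positive, so a flat
  noiseless trace can never qualify.

The noise SD is the MAD-based robust SD of the 50 ms pre-stimulus baseline;
the baseline level is that window's median. Ties between qualifying onsets
resolve to the earliest, since latency is defined from the light onset.

**Amplitude measurement.** A plain extremum over a post-onset window is
biased upward at low signal-to-noise (the extremum selects the most favorable
noise excursion). The amplitude is therefore measured in two stages: the peak
is *located* on a 1 ms-smoothed trace, and the amplitude is the mean of the
raw samples within +-0.25 ms of that location, relative to the baseline
median. On noise-free 500 pA events this measures 499.4 pA; at a
signal-to-noise ratio of 5 the bias is under +3%, against roughly +40% for a
raw extremum.

**Noise floor.** Events below `min_amplitude` are rejected; the default is
5x the robust baseline noise SD with a 5 pA absolute floor (the relative
criterion alone is degenerate on noiseless synthetic traces). At an amplitude
exactly equal to this floor, sensitivity is necessarily ~50-70% (the
measurement scatters around the threshold); the package's detection
guarantees are therefore stated over events at or above 5x the noise SD as a
population, where measured sensitivity exceeds 95%.

**Connectivity call.** `classify_cell_connectivity()` labels a cell connected
only if events are detected in *strictly more than half* of its sweeps;
occasional sweeps in which a spontaneous miniature IPSC lands inside the
detection window are thereby outvoted. Amplitude and latency are averaged
over event-bearing sweeps and reported only for connected cells.

**Quality control.** Cells with any series resistance above 25 MOhm, or more
than a 30% change relative to the first sweep, are excluded
(`qc_series_resistance()`; the first-sweep reference is the conventional
reading of "change during the recording"). Cells whose evoked current
survives gabazine *and* has sub-millisecond latency are excluded as
ChR2-contaminated — that combination is the signature of a direct
photocurrent in a recorded cell that itself expresses the opsin
(`assess_gbz_block()`, `exclude_chr2_contamination()`). A GBZ-insensitive
response with latency >= 1 ms does not meet the exclusion rule and is instead
flagged for review.

# Firing-rate suppression (loose-seal)

`detect_spikes()` band-passes the trace (100-2000 Hz, 2nd-order Butterworth,
zero-phase), thresholds at 6x the MAD-based SD of the filtered trace (1 pA
absolute floor), takes each suprathreshold excursion's extremum as the spike
time with a 2 ms refractory period, and discards excursions below 25% of the
typical detected height (band-pass ringing after a genuine spike can re-cross
a low threshold). The spike detection method is package-defined: it is a
standard extracellular pipeline, not a published prescription. The waveform
total duration — the dopamine-identity criterion, strictly >2 ms
(`check_da_waveform()`) — is the span over which the unfiltered
spike-triggered average exceeds 10% of its peak.

`compute_rates()` counts spikes in the 3 s before the train and the 3 s of
the train, per sweep; mean and SD are taken *across sweeps*. A cell is
suppressed iff the during-train mean rate is strictly below the baseline mean
minus 2 across-sweep SDs (`classify_suppression()`). A "2 SD" rule admits a
within-sweep-bins reading too; the across-sweeps interpretation is adopted
because the assay's natural presentation — a mean +- 2 SD band of the
baseline firing rate against per-sweep rasters — is defined over sweeps.
With fewer than two sweeps the SD is undefined and the cell is not
classifiable (`NA`).

Cells without tonic firing are excluded; the package operationalizes this
(the exclusion is stated without a criterion in the assay's source) as a
baseline mean below 0.5 Hz or any baseline window with a spike-free gap over
2 s (`qc_tonic_firing()`). Cells with light-evoked *excitation* that persists
under gabazine are excluded as opsin-expressing
(`exclude_light_evoked_excitation()`): during-rate above the baseline + 2 SD
band in both conditions.

The 2-SD rule has an intrinsic false-positive rate of roughly 0.1-1% per cell
(the during/baseline difference has SE ~ sigma*sqrt(2/n) against a threshold
of 2 sigma-hat), which the classifier-recovery simulations bound empirically.

# Train plasticity

`segment_train_amplitudes()` measures each of the 60 pulses against a *local*
baseline, the median of the 2 ms immediately before that pulse's onset: at
20 Hz the ~10 ms decay tail of the preceding IPSC has not fully settled, and
a global baseline would inflate later amplitudes. The noise estimate stays
global (the 2 ms local window is too short for a stable MAD). A pulse with no
detected event contributes amplitude 0 — a release failure, not missing data —
so normalized means average over failures. Amplitudes are averaged across
sweeps *before* normalization to the first pulse; `ppr` and `last_first` are
ratios of those averages, and are invariant to uniform amplitude scaling. A
cell whose first pulse evokes nothing in any sweep is non-responding and gets
no train response.

`detect_slow_current()` flags a sustained current outlasting the train: the
median of the sweep-averaged trace over 500 ms starting 25 ms after the last
pulse (past the last fast IPSC; the median is robust to residual brief
events) deviating from the pre-train baseline by more than 5x the baseline
noise SD, with a 1 pA floor for the noiseless degenerate case. The window and
threshold are package-defined; the phenomenon is reported in the source
literature without one.

# Cohort statistics

`summarize_cohort()` reports counts and integer percentages
(round-half-away-from-zero) of connected and suppressed cells, each over the
cells for which that assay was performed and classifiable, plus amplitude
(nA) and latency summaries over connected cells.

Cross-circuit comparisons use the tie-corrected Kruskal-Wallis test
(`kruskal_wallis()`, via `stats::kruskal.test`) followed by pairwise
rank-based (Wilcoxon) comparisons with discoveries controlled by the
two-stage adaptive step-up FDR procedure of Benjamini, Krieger and Yekutieli
(`bky_two_stage_fdr()`). The implementation follows the original two-stage
definition: with q' = q/(1+q), stage one runs Benjamini-Hochberg at q'; its
non-rejections estimate the number of true nulls m0; stage two reruns BH at
q' * m / m0. The choice of the pairwise post-hoc scheme is package-defined
(the source names only a multiple-comparison step after Kruskal-Wallis); the
FDR method is not.

`location_connection_regression()` fits a binomial logistic model — the
two-class case of the multinomial — of the connectivity call on the AP, ML
and DV coordinates, reporting Wald p-values per coordinate and a
likelihood-ratio test against the intercept-only model. Small cohorts make
complete separation likely; it is detected from the glm fit (fitted
probabilities at the boundary, or runaway coefficients) and handled by a
ridge-penalized IRLS refit (penalty 0.5 on the non-intercept coefficients),
flagged in the output with Wald p-values withheld rather than fabricated.

# The synthetic-data generator

Every stage above is validated against `simulate_vc_recording()`,
`simulate_loose_seal_recording()` and `simulate_cohort()`, which carry full
ground truth. Design choices, fixed once:

* **IPSC waveform**: biexponential, A * (exp(-t/tau_d) - exp(-t/tau_r)),
  normalized so the *sampled* peak equals the ground-truth amplitude exactly
  (onset snapped to the 0.1 ms sample grid); defaults 0.8 ms rise, 10 ms
  decay, 2 ms mean latency with 0.2 ms jitter, floored at one sample period.
  These produce the fast-rise, 1-5 ms-latency events the detector is defined
  on; the assay's source reports latency ranges but no kinetics.
* **Amplitudes**: cohort-level lognormal, median ~1.2 nA, sdlog 0.65,
  truncated to 0.2-4.5 nA — spanning the reported nA ranges without claiming
  per-cell values. Miniature IPSCs are Poisson (default 2 Hz) with small
  20-60 pA amplitudes so the majority-of-sweeps rule is exercised against
  realistic distractors.
* **Pharmacology**: gabazine removes evoked GABAergic IPSCs (for
  `gbz_blocks` cells) and all minis; opsin-contaminated cells instead carry a
  GBZ-insensitive inward photocurrent at 0.5 ms latency with the sustained
  time course of an opsin current (0.2 ms rise, 20 ms decay), plus
  light-locked extra spikes in loose-seal mode.
* **Spiking**: truncated-Gaussian ISI process (mean 1/rate, CV default 0.1,
  2 ms refractory floor). Suppression is implemented by *time rescaling* —
  the integrated-rate map compresses the train window by the suppression
  factor — so the ISI structure stays stationary and rate recovery is exactly
  testable; a factor of 0 silences the window completely. Spikes render as a
  biphasic single sine cycle (half-amplitude second lobe) of total duration
  2.5 ms by default, 100 pA peak over 4 pA noise.
* **Cohorts**: per-cell truth is Bernoulli in the stated probabilities, or
  fixed by explicit truth vectors in fixture mode; baseline rates are uniform
  on 2-6 Hz (within the 1-8 Hz tonic range, high enough that the 2-SD rule is
  well-posed over 10 sweeps); locations are per-circuit 3-D Gaussians.

**What the generator does not emulate** — and hence what passing tests do not
show about real recordings: seal or series-resistance drift within a sweep,
electrode artifacts, correlated (non-white) noise, bursting or pausing
structure in the spike train, rebound firing after the train, voltage-clamp
escape on nA-scale currents, and any biophysical mechanism linking circuit
identity to synapse placement. Detector and classifier guarantees are
statements about this statistical model of the recordings, not about slices.

# Numerical choices and problem sizes

Tolerance defaults: detector smoothing 0.3 ms, peak-location smoothing 1 ms,
peak average 0.5 ms, noise floor max(5x robust SD, 5 pA); spike threshold 6x
MAD with 1 pA floor; suppression and excitation bands at 2 across-sweep SDs;
FDR q = 0.05. Determinism: every simulation takes an explicit seed and
restores the caller's RNG state; `run_pipeline()` derives per-cohort seeds
from the master seed, and identical config + seed gives byte-identical
output tables.

The validation suite runs at sizes chosen to give stable Monte-Carlo
estimates at interactive runtimes: 200-250 events for detector sensitivity
and bias (hardest SNR decade, 5-10x noise), 1000 event-free sweeps for the
false-positive rate, 250 cells per arm for suppression recovery, 1000 random
p-sets for the FDR oracle comparison, and 500 null replicates at n = 30 for
the regression type-I error. The fixture cohorts reproduce the published
per-circuit percentages from their count pairs end to end.

# Known limitations

* The >50%-of-sweeps rule is applied to single-pulse protocols; how a
  multi-pulse sweep should vote is left undefined (first pulse only).
* Latency estimates carry a small early bias (~0.2 ms at high amplitude)
  because the run-start onset definition reacts to the smoothed rise; the
  noise-free error is within one sample.
* No mouse-level clustering: statistics treat cells as independent, as the
  assay's source does; a mixed-model treatment is out of scope.
* No acquisition-format readers (pClamp/Igor/Wavesurfer); conversion to the
  package's CSV + JSON layout is upstream. An HDF5/NWB container is not
  provided; cohort sizes here do not require one.
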