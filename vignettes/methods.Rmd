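---
title: "Detecting cortical up/down states and testing inhibitory control of their transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cortical up/down states and testing inhibitory control of their transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(updownphase)
```

## The problem

During slow-wave sleep and anesthesia, cortical networks alternate between
*up states* (depolarized, active) and *down states* (hyperpolarized, silent),
paced by a slow (<1 Hz) oscillation that is visible both in single-cell
membrane potential (Vm) and in the local field potential (LFP). A central
question is whether inhibitory interneurons (PV- and SST-expressing cells)
merely follow this rhythm or actively shape it — in particular, whether their
firing helps terminate the up state.

This package implements the analysis chain needed to address that question
from paired LFP/spike recordings:

1. detect up/down states from the LFP, calibrated and validated against
   Vm-derived ground truth;
2. quantify spike–LFP phase locking and how it changes when the LFP is
   shifted in time relative to the spikes (the causality analysis);
3. test for spike-triggered changes in the LFP *phase speed* near state
   ends, against matched spike-free controls;
4. test whether rare down-state spikes are real or an artifact of state
   misclassification;
5. analyse optogenetic stimulation trials (Vm and extracellular); and
6. estimate the tissue volume and cell count an optical fiber can modulate.

A first-class synthetic-data generator produces seeded recordings with known
ground truth so that every stage is testable without real data.

## State detection from the LFP

The raw LFP is low-pass filtered below 500 Hz (second-order elliptic filter,
0.1 dB passband ripple, 40 dB stopband attenuation, applied in a single
forward pass) and decimated to 1 kHz (`lowpass_downsample()`). Three
per-sample decision variables are then computed:

* **S_delta** (`s_delta()`): the instantaneous phase of the LFP is extracted
  in two low-frequency bands (0–1 Hz and 1–3 Hz, the calibrated optimum for
  these recordings) as the angle of the Hilbert analytic signal (a
  peak/trough/zero-crossing interpolation method is also provided). For each
  band, phase histograms conditional on up and on down states (36 bins of
  10°, pseudo-count 1) are calibrated on a ground-truth segmentation
  (`fit_phase_likelihoods()`). At analysis time the per-band log-likelihood
  ratios are summed and squashed through a logistic, giving a value in
  (0, 1). The exact likelihood-combination rule of the originating method is
  not uniquely specified in the literature it comes from; the
  log-likelihood-ratio + logistic construction used here is fully specified,
  monotone in the evidence, and exactly 0.5 when the bands are
  uninformative.
* **S_beta_gamma** (`s_beta_gamma()`): the 10–40 Hz envelope — band-pass,
  running RMS in a 5 ms frame, 50 ms moving-average smoothing, min–max
  normalisation to [0, 1]. Up states carry more 10–40 Hz power than down
  states, so this variable complements the phase information.
* **S_comb** (`s_comb()`): the element-wise mean of the two.

The S_comb distribution is fitted with a **mixture of three Gaussians** by
EM (`fit_gmm3()`; k-means initialisation, 10 restarts ranked by
log-likelihood, tolerance 1e-6, max 500 iterations; collapsed restarts are
discarded). Components ordered by mean represent down, indeterminate and up
states. Samples with `S_comb > mu_up − 2*sigma_up` are labelled up, samples
with `S_comb < mu_down + 2*sigma_down` down. The second inequality is the
mirrored reading of the thresholding rule: down states live at the *lowest*
S_comb values, so the down criterion must select values below the down
component's upper tail — the opposite reading would label nearly every
sample down. Morphology is then applied once, in a fixed order: gaps
shorter than the 50 ms minimum inter-state interval between same-label
states are merged (up processed before down), then labelled states shorter
than the 100 ms minimum duration are relabelled indeterminate. This order
is a package convention; a single deterministic pass makes the stage
exactly reproducible and testable against a brute-force oracle.

Ground truth for calibration comes from the membrane potential
(`detect_states_vm()`): a two-Gaussian mixture on the Vm samples with the
same ±2σ thresholding and morphology. This is a deliberately simple
amplitude-based stand-in for the cited Vm method, and it is validated on
synthetic data (per-sample agreement ≥ 95% at the default 15 mV separation
and 1 mV noise).

Validation uses per-sample ROC analysis (`roc_evaluate()`): for up
detection, true positives are samples called up by both Vm and LFP, false
positives samples called up from the LFP but down from the Vm (and
symmetrically for down). On the default 600 s synthetic recording the
detector achieves false-positive rates below 10% for both states and
AUC(S_comb) ≥ AUC(S_delta), the motivation for combining the variables.

## Spike–LFP phase locking and the time-shift causality analysis

The instantaneous phase of the 0.1–4 Hz LFP is **rescaled by its empirical
cumulative distribution** (`rescale_phase()`), making the marginal phase
distribution uniform; this removes spurious locking caused by asymmetric
LFP wave shapes. The *phase of firing* (`phase_of_firing()`) collects the
rescaled phase at each spike time; locking strength is one minus the
circular variance, i.e. the mean resultant length (`locking_strength()`),
and significance comes from the Rayleigh test (`rayleigh_test()`, Zar's
finite-sample approximation, calibrated against a Monte-Carlo null in the
test suite). The preferred phase is the circular median (ties broken toward
the smallest angle) with a circular interquartile range
(`preferred_phase()`).

For the causality analysis (`shifted_locking_profile()`) the LFP is shifted
by τ ∈ [−0.5, 0.5] s in 10 ms steps relative to the spike train. Shifting
the LFP *by τ* means the phase assigned to a spike at time *t* is the
original phase at *t − τ*: negative τ therefore probes the phase *after*
the spike, which is the only place a causal effect of the spike on the
oscillation can appear. Locking at τ ≥ 0 can be large purely through
entrainment and the autocorrelation of the phase, so the putative causal
window is the contiguous range of negative shifts, down to `tau_end`, over
which locking is both significant (Rayleigh p < 0.01, Bonferroni-corrected
by the 101-point grid) and *stronger than the maximum over τ ≥ 0*;
`tau_max` is the shift of maximal locking. `tau_end` is undefined when the
shift immediately below zero already fails, and is clamped at −0.5 s when
the run reaches the grid edge. Cells with fewer than 100 spikes are
excluded (flagged, not an error). The 10 ms grid and the Bonferroni factor
equal to the grid size are package conventions.

Per-state firing statistics (`state_firing_stats()`), strength/reliability
phase histograms per state context (`strength_reliability_histograms()`,
with transition contexts defined as 100 ms windows straddling state
boundaries — a package convention), and a circular–linear correlation
(`circ_linear_corr()`) complete the module.

### Down-state spikes and misclassification

Interneurons fire rarely during down states. To test whether those spikes
are genuine rather than artifacts of misdetected states, the probability
that a 20 ms bin is falsely called down is tabulated as a function of the
bin's S_comb value on the calibration recording
(`misclassification_table()`, Laplace-smoothed, no monotonicity enforced).
For each cell, the null probability that *all* its down-state spikes fell
in misclassified bins is the product of the table probabilities over
detected-down bins containing at least one spike
(`down_state_spike_test()`). The default multiplies one factor per bin;
a `per_spike` option multiplies one factor per spike instead, since both
formulations appear in the field's descriptions of the test.

## Spike-triggered phase speed

If inhibitory spikes precipitate the up-to-down transition, the LFP phase
should advance *faster* just after a spike than just before, specifically
near the end of up states. `phase_speed()` is the central difference of the
unwrapped phase (deg/s, unsmoothed). `collect_spike_stretches()` selects
spikes between X = 400 ms and 200 ms before the end of their state whose
±200 ms window lies entirely within the state, and averages the speed over
T = 200 ms before and after the spike (the spike sample itself belongs to
neither window; X and T defaults follow the reference analysis, and both
can be varied over their design ranges). `pre_post_test()` is the
one-tailed paired t-test (post > pre in up states, post < pre in down
states; all-zero differences return the boundary convention p = 0.5).

LFP dynamics near a state end are asymmetric even without any causal
spiking — speed rises toward the transition — so the analysis is repeated
on **matched control stretches** (`sample_control_stretches()`): for each
data stretch, a seeded draw among windows in which the cell is silent,
whose distance to the state end equals the data stretch's distance (within
one sample) and whose whole-window mean speed differs by less than
50 deg/s. Controls are sampled without replacement; the match rate is
reported. This asymmetry also makes the raw pre/post test *conservative*
on entrained-only synthetic data (the null rejection rate sits below the
nominal 5%), which the test suite checks as an upper bound.

## Optogenetic trial analyses

`detect_mua()` isolates multi-unit activity by zero-phase 4th-order
Butterworth high-pass filtering above 300 Hz and detects negative-going
crossings of 5 times the noise SD (robust MAD/0.6745 estimator by default;
plain SD available), with a 1 ms dead time. `psth()`, `spectrogram_lfp()`
(100 ms Hamming windows stepped every 1 ms, 500-point FFT, 0–100 Hz) and
`band_power()` (Welch PSD with half-window segments and 50% overlap; band
integral normalised by the total pre-stimulus power; 10 ms artefact
blanking at window starts) cover the extracellular side. Intracellular
trials are classified from the 100 ms (anesthetized) or 50 ms (awake)
pre-stimulus window: up if Vm is stably >10 mV above rest, down if stably
within ±3 mV of rest, otherwise discarded; "stably" is operationalised as
the criterion holding on ≥90% of pre-window samples (package convention).
`delta_vm()`, `transition_onset()` (first crossing of baseline ± 2 SD),
`transition_slope()` (OLS) and `channel_lag()` (Ch2 − Ch1 onset delay)
quantify the evoked transitions.

## Optical reach

Light transmission through cortical tissue is fitted with a single
exponential (optionally exponential × geometric cone spread) constrained to
1 at zero thickness (`fit_transmission()`); the maximal modulation depth
solves transmission(z) = I_z / I_{z=0} by bisection (`max_depth()`). The
illuminated volume is a cone frustum with base radius the fiber radius
(0.1 mm), height the maximal depth, and half-angle `asin(NA)`
(`frustum_volume()`); with the published inputs (NA 0.22, depths 0.32 and
1.0 mm) this convention reproduces the published volumes (0.0193 and
0.159 mm³) within 3%, whereas the tissue-refractive-index convention
`asin(NA/1.36)` misses by ~20% — which is why the in-air convention is the
default. Cell counts use the stereological formula T = N·V/t scaled by the
double-labelled fraction (`cells_in_volume()`), and
`expected_interfered_spikes()` combines count × P(active per state) ×
spikes per active state.

## The synthetic-data generator

The generator emulates the statistical structure the analyses rely on, not
the biophysics:

* `gen_state_sequence()` — alternating up/down states with
  gamma-distributed durations (shape 4, redrawn below the 100 ms minimum).
  No duration law is published for these recordings; means of 0.5 s (up)
  and 0.4 s (down) are package defaults chosen to give a ~1.1 Hz slow
  rhythm with realistic irregularity, and are explicitly *not* measured
  values.
* `gen_lfp()` — a ground-truth phase advancing piecewise-linearly through
  anchor values at state boundaries (down: 322°→45°, up: 112°→264°, the
  gaps crossed linearly across the boundary), so LFP troughs correspond to
  up states; the LFP is cos(phase) plus 10–40 Hz noise with higher
  amplitude in up states plus white noise.
* `gen_vm()` — a two-level trace (−70/−55 mV default, >10 mV separation)
  with 20 ms linear transitions and Gaussian noise.
* `gen_spikes_entrained()` — inhomogeneous Poisson spikes, state-gated and
  modulated by a max-normalised von Mises phase profile (defaults: peak
  10 Hz in up states, 0.2 Hz in down states, preferred phase 167°, κ = 2).
  This is the *entrained-only* null: spikes follow the phase but do not
  influence it.
* `gen_spikes_causal()` — the causal scenario, simulated forward in time:
  spikes are drawn as a Poisson process gated by the *current* phase, and
  each up-phase spike schedules a Gaussian speed bump in its near future,
  after which the phase is re-integrated and the LFP rebuilt. Because the
  perturbation decouples the phase from the originally drawn state
  sequence, the returned segmentation is re-derived from the perturbed
  phase (boundaries at the anchor-gap midpoints 78.5° and 293°).

The causal kernel deserves its design rationale. A constant-amplitude
additive bump (`kernel = "advance"`, retained for its exactly computable
quadrature: each bump adds `gain × width × √(2π)` degrees) cannot move the
locking maximum to negative shifts: an additive, spike-independent phase
increment contributes a deterministic offset plus accumulated noise to the
spike-triggered future phase, so the circular variance at τ = −lag can
never fall below its τ = 0 value. What the time-shifted analysis actually
detects in the causal hypothesis is that the *post-spike phase trajectory
is more stereotyped than the spike's own phase* — the spike predicts the
upcoming transition better than the current phase predicts the spike. The
default `kernel = "reset"` implements exactly that: the bump amplitude is
`causal_strength` (default 0.9) times the remaining phase distance to the
up-state offset anchor (264°), i.e. a partial phase reset that precipitates
the end of the up state. The reset *completes* `causal_lag` (default
100 ms) after the spike (the bump is centred at `lag − 2·width` with width
15 ms), so the caused configuration is in place at the nominal lag and
`shifted_locking_profile()` recovers `tau_max ≈ −causal_lag`. The causal
generator's default up-state rate is 4 Hz, sparser than the entrained
default, because the reset saturates: once a spike has driven the phase to
the up-offset anchor, later spikes in the same passage add little, and
dense firing blurs the recoverable lag. Recovering the lag to grid
precision requires analysing the generator's own phase; from the rebuilt
LFP the 0.1–4 Hz filter smears the (faster-than-band) caused transient, so
the sign of `tau_max` survives but its magnitude is attenuated toward
zero — a caveat that applies to real recordings as well.

What the generator does **not** emulate: conductance-based dynamics,
realistic broadband LFP spectra (only the slow component and one gated
band), spatial structure, bursting, or optogenetic light responses.
Passing tests on synthetic data therefore demonstrate the correctness and
calibration of the *analyses*, not the realism of the model.

## Numerical choices and degenerate inputs

* All band isolation is zero-phase. Narrow bands at very low corner
  frequencies (0.1 Hz at 1 kHz sampling) make IIR bandpass designs
  numerically fragile, so band isolation is FFT-domain multiplication with
  raised-cosine transition edges (10% of the corner, minimum 0.05 Hz); the
  decimation filter is the published elliptic design applied forward (its
  sub-millisecond group delay is irrelevant at 1 kHz, and a
  forward-backward pass would double the published passband ripple).
* Angles are degrees in [0, 360) at every interface; sample *i* covers the
  half-open interval [t0 + (i−1)/fs, t0 + i/fs); spikes map to phase
  samples by nearest-sample rounding (1 ms ≪ the phase timescale).
* The EM fit thins inputs longer than 1e5 samples evenly before fitting
  (the mixture shape is unaffected; determinism is preserved).
* Degenerate inputs error early and informatively: unimodal Vm, constant
  S_beta_gamma input (all-zero output with a warning), collapsed EM
  restarts, crossed thresholds, too-few spikes/states/occurrences.
* All stochastic stages take explicit seeds; generators restore the global
  RNG state on exit. `run_pipeline()` derives per-stage seeds from one
  master seed and produces byte-identical outputs on reruns.

## Problem sizes used in the validation suite

The shipped tests validate on 600 s recordings for detection (one seed),
20 seeds × 300 s for causal-lag recovery and the entrained control, one
750 s causal recording (≥ 200 stretches) plus 100 seeds × 150 s for the
phase-speed type-I rate, 5000 replicates (n = 1000) for Rayleigh
calibration, and 1e5-sample draws for the resultant-length and rescaling
checks. These sizes are the package's chosen compromise between
Monte-Carlo error and runtime; the same code runs unchanged at larger
sizes.

## Known limitations

* The Vm ground-truth detector is amplitude-based and simpler than the
  cited construction; with low Vm separation or heavy noise its ±2σ
  thresholds can overlap and error.
* S_delta's likelihood-combination rule is a reconstruction (see above),
  not a line-by-line port of the originating MATLAB implementation.
* `tau_end` statistics on entrained-only data are conservative by design;
  the causal-window definition deliberately discards any effect that does
  not exceed all non-causal (τ ≥ 0) locking.
* The phase-speed pre/post test inherits the state-end asymmetry of the
  slow oscillation; conclusions should always be drawn relative to the
  matched controls, not from the raw test alone.
* File I/O is plain text (CSV/TSV, one-spike-per-line); no binary
  container formats are read or written.
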