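---
title: "Closed-loop seizure analysis with ictaloop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop seizure analysis with ictaloop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictaloop)
```

## What the package models

`ictaloop` implements the computational chain of a closed-loop seizure
experiment: epileptiform spikes are detected on a hippocampal local field
potential (LFP), clusters of spikes are segmented into electrographic
seizures, an online (causal) version of the detector triggers light delivery
to an inhibitory opsin, and the effect of that intervention is quantified as
a change in seizure duration measured from the trigger. Two companion
analyses operate on the same event stream: peri-event ΔF/F analysis of
two-photon calcium traces from imaged neurons, and onset-pattern
classification of human stereo-EEG (sEEG) channels, comparing the fasciola
cinereum (FC) of the posterior hippocampal tail against the amygdala /
anterior hippocampus (AH).

Every stage is driven by a synthetic-session generator with complete ground
truth, so the whole pipeline is testable without any experimental recording.

## The synthetic session generator

`generate_lfp()` builds a session as Gaussian white noise (optionally with a
1/f component) into which a canonical biphasic spike transient is added:

* **Spike waveform.** A sharp negative half-sine deflection (first half of
  the 40 ms default width) followed by a slower positive rebound at 40% of
  the amplitude. No published waveform is prescribed for this preparation;
  any sharp transient exercises the amplitude, width and template criteria,
  which is the purpose of the generator. Amplitude is expressed in noise-SD
  units, so "SNR 8" means the trough is 8 robust SDs of the raw noise.
* **Interictal spikes.** A homogeneous Poisson process (default 0.1/s),
  thinned within 3 s of any seizure so that truth labels stay unambiguous.
* **Seizures.** Onsets are Poisson (overlapping draws thinned, first onset
  wins), durations lognormal, and within-seizure interspike intervals (ISIs)
  truncated-normal with mean below 1 s — so every generated seizure
  satisfies the cluster-inclusion rule by construction. Seizures are
  realized purely as spike clusters.
* **Light intervention.** `apply_intervention()` models the optogenetic
  effect as a multiplicative truncation of the post-trigger seizure
  duration: the new offset is `trigger + factor * (offset - trigger)`,
  truth spikes beyond it are deleted and their waveforms subtracted from
  the signal. Factors above 1 (lengthening) are not modeled.
* **Calcium.** Each cell's latent activity receives an impulse per spike
  and a sustained unit-plateau elevation during seizures, convolved with a
  difference-of-exponentials indicator kernel (rise 50 ms, decay 500 ms,
  evaluated analytically on the 15.49 Hz frame grid), on a resting
  fluorescence of 1 unit so ΔF/F is well defined. Movie rendering draws
  each cell as a disk whose pixel mean equals the trace value, making
  mask-based extraction an exact round trip in the noise-free case.
* **sEEG.** Per seizure and per channel, an ictal discharge is inserted
  with a region-specific involvement probability and onset latency; the
  emitted onset table is the ground truth for classification.

Randomness derives from a single top-level seed: every sub-generator
(noise, events, each calcium cell, sEEG) uses an independent stream derived
by a fixed integer mix, so adding cells never perturbs the LFP noise.
Identical seeds give bit-identical output. Times are seconds from recording
start, intervals half-open `[start, end)`.

What the generator does *not* emulate: biophysical network dynamics,
realistic kainate pathophysiology, electrode drift, movement artifact
spectra, or video-EEG semiology. Passing tests therefore demonstrate that
the *analysis chain* is correct and calibrated, not that the detector's
default criteria are optimal for any particular animal.

## Spike detection

Detection is criterion-based, mirroring detector software in which the
experimenter supplies per-criterion values that are combined by Boolean
logic:

| parameter | default | note |
|---|---|---|
| band | 5–40 Hz | Butterworth, order 4; zero-phase offline, causal online |
| threshold | 5 robust SD | robust SD = 1.4826 × MAD of the filtered trace |
| width bounds | 10–80 ms | full width at half maximum |
| template score | ≥ 0.6 | normalized cross-correlation, ±5 ms jitter |
| refractory | 100 ms | earlier candidate wins |

The robust (MAD-based) SD is used instead of the plain SD so that
seizure-dense records do not inflate their own threshold; detection is
consequently invariant to rescaling the signal. The template score selects
the jitter shift with the largest correlation magnitude and returns its
signed value, so an exact sign inversion scores −1. Artifact rejection vetoes
events within a configurable pad (closed boundary) of saturated samples or
of windows with excess broadband power. The Boolean rule is an arbitrary
AND/OR/NOT expression over the flags; the default accepts
`(amplitude AND width) AND NOT artifact`, with a template clause added when
a template is configured.

## Seizure segmentation

Two rules govern segmentation: spikes with ISIs under `max_isi` (default
1 s) form a cluster, and a seizure is not considered ended until the
spiking rate falls below one spike per `end_gap` (default 2 s). The two
rules can disagree for trailing ISIs in `[1, 2)` s; the package resolves
this by letting clusters *form* at the 1 s rule but *extend* through
trailing gaps below 2 s before terminating, because the termination rule is
explicitly a rate criterion. Gap comparisons use `>=` for termination and
`<` for inclusion, everywhere. A cluster must contain at least
`min_spikes = 3` spikes at the 1 s rule to count as a seizure — singletons
and pairs are interictal events, matching the distinction between
interictal spikes and spike-cluster seizures. Segmentation is validated
against an independent brute-force scanner exhaustively on all trains over
an 8-point grid and on 1,000 random trains.

The analysis duration of a detected seizure is `end − trigger`, i.e. from
the closed-loop trigger to the seizure's end, which is what the
intervention statistics consume.

## The streaming (online) detector

`stream_detect()` is a causal re-implementation of the same criteria: a
forward-only Butterworth filter (state carried across chunks, bit-exact for
any chunking including sample-by-sample replay), a running robust-SD
threshold re-estimated every 5 s from a trailing 15 s baseline buffer
(detection is disabled during the initial warm-up), excursion-extremum
spike detection with refractory, and an N-spikes-in-window trigger
(default: 3 spikes within 2 s) with lockout. The N-in-window rule is the
minimal trigger consistent with spike-cluster seizures and permits latency
analysis; its parameters are experimenter inputs, as they were per-animal
in practice. Light delivery supports two modes: continuous light from
trigger to seizure end (the optogenetic inhibition setting), and a fixed
pulse train (2 s on / 6 s period / 10 min — the 33% duty-cycle labeling
protocol).

The default lockout is 30 s, which prevents re-triggering within one
seizure in sparse recordings. The recovery experiments below use 5 s,
because their sessions generate seizures as little as 3 s apart and a 30 s
lockout would silently skip seizures and bias triggers toward mid-seizure
times.

## Intervention statistics

Durations from trigger, labeled light-on / light-off per animal, feed
three estimators:

* `normalized_duration()`: per animal, mean on-duration / mean
  off-duration × 100; the group summary is the mean ± s.e.m. *across
  animals*, never across seizures. The ratio is scale-invariant per animal.
* `mixed_model_duration()`: duration ~ condition + (1 | animal), fitted by
  REML (lme4) with the condition F test by Satterthwaite's method
  (lmerTest). This random-intercept structure is the minimal two-level
  model for thousands of seizures nested in a handful of animals;
  alternatives (e.g. random slopes) can be fitted on the returned data.
* `group_ttest()`: two-tailed two-sample t test on the per-animal
  normalized percentages between an opsin and a control group.

## Problem sizes and calibration

The packaged acceptance analyses use the following sizes, chosen as the
smallest designs that give stable estimates of the properties under test:

* **Detection**: 10-minute sessions at 500 Hz, at SNR 6 (the boundary of
  the stated operating range) and SNR 8. Offline sensitivity is ≥ 0.95
  with ≤ 2 false positives/min at ±25 ms matching tolerance.
* **Recovery**: truncation factors {1.0, 0.75, 0.5} × 7 replicate seeds,
  each batch simulating 4 animals end-to-end (signal → causal detection →
  truncation → offline re-segmentation), ≥ 100 seizures per animal across
  its light-on and light-off sessions. Sessions are ~32 min at 500 Hz with
  lognormal seizure durations of median 12 s and 0.2 s ictal ISIs: the
  durations are deliberately long relative to the ISI because the measured
  end of a seizure is its last detected spike, which trails the true
  offset by about half an ISI — a discretization that would otherwise bias
  the on/off ratio downward at small truncation factors. The group
  estimate must be monotone in the factor and cover the truth within the
  2-SD replicate-seed band in ≥ 90% of batches.
* **Mixed-model calibration**: 500 null tables (factor 1.0, 4 animals ×
  100 seizures per cell, lognormal with an animal random intercept);
  rejection at α = 0.05 must land in [0.03, 0.07]. Power at factor 0.5 is
  estimated from 300 such tables at p < 0.01.
* **Calcium**: 300 s sessions, 12 cells; the movie round trip must be
  exact to 1e−6 relative; spike-aligned averages must rise after time 0
  for ≥ 90% of cells; seizure-end-aligned averages must decay; the
  activity–spiking correlation must exceed its 100-permutation null.

## ΔF/F and peri-event choices

The ΔF/F baseline is a rolling 8th-percentile of the raw trace over a 30 s
centred window (shrunken at the edges) — a standard low-quantile baseline
for indicator imaging that is exactly testable; both values are arguments.
Peri-event alignment assigns each bin the frame nearest its centre (making
the matrix bit-reproducible), averages across events on the relative-time
grid, and tracks per-bin usable-event counts for windows clipped at the
recording edges. Heat-map row ordering by peak time is available but
cosmetic. The activity–spiking correlation bins spikes at one frame period,
interpolates the rate onto frame times, and uses the product-moment
estimator per cell; estimator and binning are arguments since no single
convention is canonical.

## sEEG onset classification

`classify_onset()` applies the differential-onset rule: clear ictal onsets
in FC and AH separated by 50 ms or more mean the seizure spread from the
earlier region; under 50 ms is simultaneous; exactly 50 ms counts as
differential (the rule is "50 ms or more"). A region with no marked onset
is not involved, giving the `*_without_*` and `neither` labels. Onset times
are inputs — expert-marked in clinical practice, generator truth in tests;
automated marking of human ictal onsets is out of scope, though per-channel
first-spike times from the segmenter can be supplied. Involvement fractions
are kept exact and rounded to integer percent only at report time. The
80–250 Hz marker band-passes the channel, takes the analytic-signal
envelope (FFT Hilbert transform), and flags windows whose mean envelope
exceeds a robust-SD threshold above the median — a screening marker for
high-frequency oscillations, not a validated clinical HFO detector.

## Numerical conventions and degenerate inputs

* Sample `i` (1-based) occurs at `t0 + (i−1)/fs`; intervals are half-open.
* Zero-variance signals yield empty candidate lists, not errors; flat
  measurement windows report zero amplitude and width and fail the width
  flag; zero-variance template windows score 0.
* Coincident candidates resolve to the earlier time, then the larger
  amplitude; refractory suppression is earliest-wins.
* Sessions too short to hold a seizure are flagged
  (`no_seizures_possible`), with empty event lists; nonpositive rates give
  empty event lists.
* Cells whose ΔF/F maximum is not positive are dropped from
  max-normalization with a warning; zero-variance cells are excluded from
  the correlation summary.
* Singular mixed-model fits are reported in the result object, never
  silenced.

## Known limitations

The generator's spike waveform, SNR and rate defaults are free parameters
of the synthetic model, not claims about any recording; detector defaults
are starting points that a real experiment would tune per animal. The
streaming detector freezes no state across sessions and models no hardware
latency. The sEEG stage classifies expert-style onset tables; it does not
localize onsets from raw traces. Seizure-duration recovery is demonstrated
for multiplicative truncation — other intervention effect shapes (e.g.
probabilistic abortion of seizures) would need their own generator mode.
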