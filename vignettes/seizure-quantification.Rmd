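---
title: "Quantifying electrographic and behavioral seizures in chronic rodent LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying electrographic and behavioral seizures in chronic rodent LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictalkit)
```

## The problem

Chronic intrahippocampal-kainate models of temporal lobe epilepsy generate
weeks of continuous single-channel local field potential (LFP) data per
animal. Electrographic seizures occur tens of times per hour, far too often
for manual scoring, while overt motor seizures (large behavioral seizures,
LBSs, extended Racine stage > 3) are rare and must be found in the LFP so
that the video can be reviewed and scored by a human. `ictalkit`
implements both automated stages — an ictal spike counter with seizure
assembly rules, and an envelope-threshold LBS flagger — together with the
behavioral metrics used alongside them, and a ground-truthed synthetic LFP
generator against which every stage is validated.

## The detection model

### Baseline amplitude

All detection thresholds are multiples of a per-recording *baseline
amplitude*. The natural definition is the mean rectified amplitude
`mean(|x - mean(x)|)`, but a plain mean is inflated by the very seizures
being detected. The default estimator is therefore

```
baseline = 1.18294 * median(|x - mean(x)|)
```

where 1.18294 is the Gaussian ratio of the mean to the median absolute
deviation, making the estimate a robust *rectified-mean equivalent*: on
pure Gaussian background the two definitions agree, and a seizure
occupying ≤ 10% of the recording moves the median-based estimate by well
under 10%. Closed forms used in the tests: a pure sine of peak `A` gives
`1.18294 A / sqrt(2) = 0.8365 A` (robust) and `2A/pi = 0.6366 A` (plain
rectified mean). `method = "mean"` restores the literal definition.

### Spike detection

A spike is a local extremum of the rectified, mean-subtracted signal
exceeding `spike_threshold_factor` (default 2) times the baseline
amplitude. Both polarities count: thresholds operate on `|x - mean(x)|`.
Two morphological constraints follow:

* **Width.** The width is the duration of the contiguous run of rectified
  signal at or above *half the detection threshold* that contains the
  peak, and must lie in `[spike_width_min_ms, spike_width_max_ms]`
  (defaults 5–200 ms). Measuring at half threshold rather than half peak
  keeps the rule stable for spikes barely above threshold. The rule also
  does the heavy lifting against false positives: in slow-wave-dominated
  background, suprathreshold excursions are wide (> 200 ms) and are
  rejected wholesale.
* **Refractory interval.** Retained spikes are at least
  `min_interspike_interval_ms` (default 40 ms) apart; within that window
  the larger rectified peak wins, the earlier one on an exact tie, which
  makes output deterministic.

The original workflow customized spike width and inter-spike bounds per
subject without publishing values; the defaults here are declared,
configurable values, not published ones.

### Seizure assembly

The published global criteria are: at least 4 spikes exceeding twice the
baseline amplitude within each 2 s bin; interictal periods of at least
1 s; minimum seizure duration 3 s (with the duration threshold swept in a
separate analysis). Two readings of "each 2 s bin" exist, and both are
implemented:

* **Sliding (default).** A time point is ictal when the 2 s window
  centered on it holds ≥ 4 spikes. This is the only reading under which a
  1 s interictal minimum is meaningful — tumbling 2 s bins cannot resolve
  sub-2 s gaps.
* **Tumbling** (`mode = "tumbling"`), counting spikes in fixed
  consecutive 2 s bins, for comparison with fixed-bin implementations.

The interictal rule is applied to *spike-free time*: a gap of ≥ 1 s
between consecutive spikes is interictal and terminates any event, so
spikes are first split into clusters at such gaps and the window rule is
evaluated within clusters. The alternative — merging sliding-window ictal
regions across spike-free gaps — was rejected because a 2 s window
straddling, say, a 1.5 s silent gap can count 2 + 2 spikes and weld what
are plainly two events separated by more than the interictal minimum into
one. Under the clustered reading, trains separated by 0.8 s merge and
trains separated by 1.5 s split, which is the behavior the stated rules
describe.

Event boundaries are trimmed to the first and last spike the event
contains (otherwise duration statistics would depend on the window
length), all threshold comparisons are inclusive (`>=`), matching the
"minimum" phrasing throughout, and events shorter than
`min_seizure_duration_s` are discarded. Hippocampal paroxysmal
discharges (HPDs) are the subset of events with mean spike rate ≥ 5 Hz
and duration ≥ 5 s, both inclusive — an event at exactly 5 Hz and 5 s
qualifies.

`assemble_seizures` is checked exactly, on a thousand random spike
trains, against an independent brute-force oracle that enumerates all
spike pairs and applies the rules literally.

### The LBS flagger

The flagger reproduces the published envelope pipeline: FFT the raw
trace, zero all coefficients outside 20–200 Hz, magnitude of the inverse
FFT, zero-phase second-order Butterworth low-pass (0.1 Hz), threshold.
Two deliberate interpretations are documented:

* The printed index arithmetic `fdata(1:floor(20/fs)) = 0` divides a
  frequency by a sampling rate where a bin index `floor(f*N/fs)` is
  required; at any realistic `fs` the printed indices collapse to 0 and
  the operation is a no-op. The corrected bin indexing is the default;
  `mode = "printed"` preserves the literal arithmetic for comparison and
  is tested to be exactly that no-op at 1 kHz.
* Zeroing "everything outside the band" in a spectrum stored with
  negative frequencies in the upper half removes the entire negative-
  frequency half — producing an analytic-like signal whose magnitude is
  the conventional amplitude envelope. That is what `mode = "analytic"`
  (the default) does, with the factor-2 restoration of one-sided power,
  so an in-band sine of amplitude `A` yields a flat envelope at `A`
  (ripple < 5%). `mode = "symmetric"` instead zeroes symmetrically and
  returns the rectified real band-limited signal.

The smoother parameterizes the printed normalized cutoff `0.1/500` as
0.1 Hz assuming 1 kHz sampling, so other sampling rates behave
equivalently. It is applied forward and backward (zero phase, effective
order 4) with odd-reflection padding of three filter time constants;
each pass is run relative to its first sample, so a constant envelope is
reproduced exactly and a step input is crossed at its midpoint with no
lag. Flagged intervals are maximal suprathreshold runs of the smoothed
envelope, merged when separated by less than `min_flag_gap_s` (10 s).

Review thresholds were hand-tuned per subject in the original workflow.
`suggest_threshold()` proposes `k = 5` times the median smoothed
envelope: homogeneous in the trace amplitude, far above seizure-free
background (the smoothed envelope of stationary background hugs its
median, so saline recordings yield zero flags), and far below the
envelope of LBS-band activity at the amplitudes the flagger must catch.

### Behavioral metrics

The discrimination index is reported on the ×100 scale,
`100 (novel − familiar)/(novel + familiar)`, because the published DI
values (≈ 20) and the training-bias exclusion threshold (|DI| > 20) only
make sense there. Exclusion rules use the quoted strict inequalities:
testing-session total exploration < 3 s, or training |DI| > 20; a subject
at exactly 3 s or exactly DI 20 is kept. Sucrose-consumption summaries
average grams per day within day type (water-only days: both bottles;
sucrose days: the sucrose bottle). LBS burden counts Racine stages
strictly above 3 and reports rates per day, mean LBS duration, and the
median stage among LBSs. Exploration bouts are taken as raw seconds; no
rounding is applied before averaging.

## The synthetic ground truth

No recordings are distributed with the model this package reimplements,
so validation rests on a generator whose embedded events are known
exactly.

* **Background** is 1/f-family noise — amplitude spectrum
  `f^-1.5` (power `f^-3`) above a 0.5 Hz corner — plus a low-amplitude
  8 Hz theta (25% of total RMS) and 40 Hz gamma (10%) component, scaled
  to 50 µV RMS at 1 kHz. The steep exponent, within the 2–4 power-law
  power range reported for hippocampal LFP, concentrates energy below a
  few Hz: suprathreshold background excursions are then slow and wide,
  which is the regime the spike-width rule is designed to reject. The
  recording sampling rate of the original system is not stated; 1 kHz is
  assumed for defaults, and every operation takes the rate explicitly.
* **Electrographic seizures** are trains of biphasic transients (sharp
  lobe with FWHM drawn from 10–50 ms, slower opposite lobe at roughly
  half amplitude) at a programmed rate with uniform ±20% inter-spike
  jitter — predictable per-bin counts without metronomic artifacts. The
  background inside an event is attenuated to 30% amplitude (half-cosine
  ramps), reflecting that ictal discharges dominate the field potential;
  without this, slow-wave excursions comparable to a 4× spike
  occasionally cancel it below threshold and the ground truth would
  claim suprathreshold spikes the trace does not contain.
* **LBS episodes** are sustained 20–200 Hz band-limited noise bursts at
  8× baseline RMS with tapered edges — the band the flagger passes, at
  the amplitude scale of movement-contaminated convulsive recordings.
* **Artifacts** are isolated biphasic transients at 2–3× baseline,
  Poisson at 1/min: single spikes that must not assemble under the
  4-per-bin rule, stressing the false-positive path.

Scenario defaults mirror the published burden figures: seizure durations
U(4, 12) s (median 8 s, against a reported median near 7.9 s), LBS
durations U(30, 60) s (reported means 44–49 s), rates of 20 events/h for
the chronic scenario (reported 20 ± 7 events/h). Cohorts place events one
per equal time slot with ≥ 10 s separation, so programmed counts are
exact and events never overlap.

What the generator does *not* emulate: state transitions (sleep/wake
spectra), electrode drift, line noise, genuine postictal suppression, or
the morphology diversity of real ictal discharges. Passing the synthetic
suites therefore shows the algorithms implement their rules correctly
and behave sensibly on plausible signals — not that the defaults are
optimal for any particular laboratory's recordings, which is precisely
why every threshold is a per-subject parameter.

## Numerical choices and degenerate inputs

* Event times are seconds from recording start on half-open intervals;
  ties in the refractory rule break to the earlier peak; CSV times carry
  3 decimals.
* Constant or all-zero traces are a "degenerate signal" error in the
  baseline estimator (and hence the detector, unless an explicit
  baseline is supplied); a zero-median envelope is a "degenerate
  envelope" error in threshold suggestion.
* Baseline estimation requires ≥ 10 s of data; threshold suggestion
  requires ≥ 1 h unless overridden, because the envelope median must be
  dominated by inter-ictal data.
* The EDF writer emits 16-bit samples with a symmetric physical range,
  so the round-trip error is bounded by `max|x|/32767`; traces are
  zero-padded to whole one-second records.

## Validation scale

The shipped validation (tests and `scripts/acceptance.R`) uses 100 h of
synthetic saline-like recording for the false-positive bound (the
published saline observation is about one seizure-like event per 20 h),
a 4-subject, 20-LBS cohort for flagger sensitivity (the published tool
flagged all LBSs in its testing dataset), a 5–40 events/h sweep (75
embedded seizures) for recovery and rate accuracy, and 1000 random spike
trains for oracle equivalence. These sizes keep the full validation in
the tens of minutes on one core while leaving the binomial slack of each
criterion small.
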