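# ictalkit

Automated seizure quantification for chronic single-channel local field
potential (LFP) recordings from rodent models of temporal lobe epilepsy
(e.g., the intrahippocampal kainate model), for labs that record weeks of
continuous hippocampal LFP per animal and need electrographic seizure
burdens and a reviewable shortlist of likely convulsive (large behavioral)
seizures without manual scoring of thousands of hours.

## What it computes

**Electrographic seizures.** Ictal spikes are local extrema of the
rectified, mean-subtracted signal exceeding a threshold of
`k_thr x baseline` (default `k_thr = 2`, baseline = robust rectified-mean
amplitude of the recording), subject to width (5–200 ms at half
threshold) and refractory (40 ms) constraints. A seizure requires at
least 4 spikes within each 2 s sliding bin, ends at any spike-free gap of
at least 1 s (interictal minimum), and must last at least 3 s (the
duration threshold is also swept to produce frequency-by-duration
distributions). Hippocampal paroxysmal discharges (HPDs) are events with
mean spike rate >= 5 Hz and duration >= 5 s.

**Large behavioral seizures (LBSs).** Candidate convulsive events are
flagged by the envelope pipeline

```
E = | ifft( bandpass_{20-200 Hz}( fft(x) ) ) |
S = filtfilt( butter(2, 0.1 Hz), E )
flag maximal runs of S > threshold (per subject)
```

with a per-subject review threshold (suggested as 5x the median smoothed
envelope). Flagged sections go to a human for extended-Racine scoring
(stages 1–8; LBS = stage > 3), and the scores feed per-subject LBS burden
summaries.

**Behavioral metrics.** Discrimination index
`DI = 100 (novel - familiar) / (novel + familiar)`, the pre-established
memory-test exclusions (testing exploration < 3 s, training |DI| > 20),
and two-bottle sucrose-consumption summaries.

**Synthetic ground truth.** A generator produces saline-like background
(1/f-family noise plus low-amplitude theta and gamma), embedded ictal
spike trains, LBS-band bursts, and artifact transients, with exact event
labels — every detector stage is validated against it.

## Worked example

```r
library(ictalkit)

# a ground-truthed hour with 20 embedded seizures and 2 LBS episodes
scenario <- list(subjects = list(list(
  id = "demo", duration_s = 3600, artifact_rate_per_min = 1,
  seizures = list(rate_per_h = 20, spike_rate_hz = 8, amplitude_factor = 4),
  lbs = list(n = 2, amplitude_factor = 8)
)))
subj <- generate_cohort(scenario, seed = 7)$demo

params <- detection_params()         # published global defaults
spikes <- detect_spikes(subj$recording, params)
events <- assemble_seizures(spikes, 3600, params)
summarize_subject(events, analyzed_hours = 1)
#>   n_events events_per_hour mean_duration_s median_duration_s n_hpd hpd_per_hour
#> 1       22              22        10.81405             8.158    20           20

flags <- flag_lbs(subj$recording, lbs_flag_params())
flags$candidates
#>    start_s    end_s peak_envelope_uv
#> 1 1833.311 1868.643         413.3423
#> 2 3513.467 3571.087         418.1766
```

22 detected events against 20 programmed plus 2 embedded LBS episodes
(which are themselves electrographic seizures and are counted as such);
both LBS episodes — and nothing else — are flagged for review. On
seizure-free saline-like background the same defaults report well under
one seizure-like event per 20 h.

The same pipeline is scriptable from a shell:

```sh
exec/ictal simulate --scenario scenario.yaml --out-dir out --seed 7
exec/ictal detect   --input out/demo.edf --out-dir out
exec/ictal flag-lbs --input out/demo.edf --out out/review_queue.csv
```

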