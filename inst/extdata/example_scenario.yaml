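# Two-subject demonstration scenario: one chronic-epileptic hour and one
# saline-like control hour. See ?generate_cohort for the field reference.
subjects:
- id: epileptic01
  duration_s: 3600
  rms_uv: 50
  artifact_rate_per_min: 1
  seizures:
    rate_per_h: 20
    spike_rate_hz: 8
    amplitude_factor: 4
    duration_range: [4, 12]
  lbs:
    n: 2
    amplitude_factor: 8
    duration_range: [30, 60]
- id: saline01
  duration_s: 3600
  rms_uv: 50
  artifact_rate_per_min: 1
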