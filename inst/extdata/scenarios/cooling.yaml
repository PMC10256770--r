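name: cooling
kind: temperature_log
rate: -20.5
T_start: 0
T_end: -150
noise_sd: 0.5
anneal:
  T_C: -122
  duration_min: 25
# fit the active ramp through the ice-risk zone, above the -122 C anneal
T_high: -40.8
T_low: -120
critical: 2
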