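name: nanowarming
kind: temperature_log
rate: 72
T_start: -150
T_end: -25
noise_sd: 0.5
T_high: -40.8
T_low: -128.3
critical: 50
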