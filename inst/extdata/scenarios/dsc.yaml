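name: dsc
kind: dsc
rates: [1, 2, 4, 8]
targets: [5, 1, 0.1, 0.01]
threshold: 0.5
latent_heat_ref: 334
noise_sd: 0
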