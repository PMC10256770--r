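name: transplant
kind: transplant
n_animals: 5
variable: creatinine
compare_days: [2, 28]
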