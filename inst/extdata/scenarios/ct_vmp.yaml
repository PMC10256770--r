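name: ct_vmp
kind: ct_phantom
scenario: vmp_kidney
threshold: 400
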