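name: VMP loading
cpa: VMP
carrier: LM5-XZ
segments:
- kind: flush
  c_start: 0.0
  c_end: 0.0
  pressure: 40.0
  temperature: 4.0
  duration: 20.0
- kind: ramp
  c_start: 0.0
  c_end: 5000.0
  pressure: 40.0
  temperature: 4.0
  rate: 50.0
- kind: hold
  c_start: 5000.0
  c_end: 5000.0
  pressure: 40.0
  temperature: 4.0
  duration: 10.0
- kind: step
  c_start: 8400.0
  c_end: 8400.0
  pressure: 60.0
  temperature: 4.0
  duration: 25.0
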