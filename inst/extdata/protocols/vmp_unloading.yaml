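name: VMP unloading
cpa: VMP
carrier: LM5-XZ
segments:
- kind: hold
  c_start: 4200.0
  c_end: 4200.0
  pressure: 40.0
  temperature: 2.0
  duration: 15.0
  adjunct:
    name: mannitol
    c_start: 300.0
    c_end: 300.0
- kind: ramp
  c_start: 4200.0
  c_end: 0.0
  pressure: 40.0
  temperature: 2.0
  rate: -35.0
  adjunct:
    name: mannitol
    c_start: 300.0
    c_end: 0.0
- kind: flush
  c_start: 0.0
  c_end: 0.0
  pressure: 40.0
  temperature: 2.0
  duration: 30.0
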