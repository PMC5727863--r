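fields:
  lvef: number
  creatinine: number
  renal_insufficiency: boolean
  complication: boolean
  age: number
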