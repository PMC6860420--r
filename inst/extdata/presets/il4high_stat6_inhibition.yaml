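name: "il4high_stat6_inhibition"
description: "High IL-4 production with STAT6 inhibition, a 90% decrease in the binding rate between STAT6 and the activated IL-4 receptor complex"
horizon: 48
perturbations:
  - kind: "production_scale"
    target: "IL4"
    factor: 10
  - kind: "rate_scale"
    target: "kf8"
    factor: 0.1
readouts:
  - "iNOS"
  - "TNFa"
  - "IL12"
  - "CXCL9"
  - "CXCL10"
  - "IFNg"
  - "Arg1"
  - "IL10"
  - "VEGF"
normalization:
  mode: "to_t0"
seed: 1
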