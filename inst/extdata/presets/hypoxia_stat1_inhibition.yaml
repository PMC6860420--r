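name: "hypoxia_stat1_inhibition"
description: "Hypoxia with STAT1 inhibition, modeled as a 90% decrease in the binding rate between STAT1 and the activated IFN-gamma receptor complex"
oxygen:
  percent: 2
  time: 0
horizon: 48
perturbations:
  - kind: "rate_scale"
    target: "kf63"
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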