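name: "hypoxia_control"
description: "Hypoxia (2% O2) alone; upregulates both M1 and M2 markers"
oxygen:
  percent: 2
  time: 0
horizon: 48
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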