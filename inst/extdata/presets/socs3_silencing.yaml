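name: "socs3_silencing"
description: "SOCS3 silencing (0 initial level, 0 production) under IFN-gamma; augments M1 marker expression"
stimuli:
  - ligand: "IFNg"
    dose: 10
    mol_weight: 17000
    time: 0
horizon: 48
perturbations:
  - kind: "silence"
    target: "SOCS3"
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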