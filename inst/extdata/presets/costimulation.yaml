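name: "costimulation"
description: "Simultaneous IFN-gamma (10 ng/ml) and IL-4 (5 ng/ml); mixed M1/M2 marker induction"
stimuli:
  - ligand: "IFNg"
    dose: 10
    mol_weight: 17000
    time: 0
  - ligand: "IL4"
    dose: 5
    mol_weight: 14000
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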