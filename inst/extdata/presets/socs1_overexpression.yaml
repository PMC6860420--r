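name: "socs1_overexpression"
description: "SOCS1 overexpression (50x initial level, normal production) under IFN-gamma; suppresses peak STAT1 phosphorylation"
stimuli:
  - ligand: "IFNg"
    dose: 10
    mol_weight: 17000
    time: 0
horizon: 48
perturbations:
  - kind: "overexpress"
    target: "SOCS1"
    factor: 50
readouts:
  - "pSTAT1d_n"
  - "pSTAT1c"
  - "IRF1"
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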