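name: "sequential_il4_then_ifng"
description: "IL-4 at 0 h followed by IFN-gamma at 1 h; delayed IFN-gamma lowers active AKT relative to IL-4 alone"
stimuli:
  - ligand: "IL4"
    dose: 10
    mol_weight: 14000
    time: 0
  - ligand: "IFNg"
    dose: 20
    mol_weight: 17000
    time: 1
horizon: 48
readouts:
  - "pAKT"
  - "pSTAT6d_n"
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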