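name: "sequential_ifng_then_il4"
description: "IFN-gamma at 0 h followed by IL-4 at 4 h; delayed IL-4 lowers IRF-1 relative to IFN-gamma alone"
stimuli:
  - ligand: "IFNg"
    dose: 10
    mol_weight: 17000
    time: 0
  - ligand: "IL4"
    dose: 20
    mol_weight: 14000
    time: 4
horizon: 48
readouts:
  - "IRF1"
  - "pSTAT1d_n"
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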