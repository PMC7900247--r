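schema_version: 1
family: gabaa_alpha1
description: >
  Fast GABA-A receptor (alpha1-containing): dominant cleft-driven component
  of the phasic IPSC, with a desensitised state shaping the current tail.
states: [C0, C1, C2, O, D]
open: [O]
e_rev_mV: -65.0
q10: 2.4
t_orig_C: 30
access: {direct: 1.0, spill: 0.2}
transitions:
  - {from: C0, to: C1, rate: 20.0, ligand: direct}
  - {from: C1, to: C0, rate: 1.0}
  - {from: C1, to: C2, rate: 10.0, ligand: direct}
  - {from: C2, to: C1, rate: 2.0}
  - {from: C2, to: O, rate: 5.0}
  - {from: O, to: C2, rate: 0.35}
  - {from: C2, to: D, rate: 1.0}
  - {from: D, to: C2, rate: 0.03}
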