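schema_version: 1
family: gabaa_alpha6
description: >
  Slow high-affinity GABA-A receptor (alpha6-containing): driven mainly by
  glomerular spillover, produces the sustained component of inhibition.
states: [C0, C1, C2, O, D]
open: [O]
e_rev_mV: -65.0
q10: 2.4
t_orig_C: 30
access: {direct: 0.3, spill: 1.0}
transitions:
  - {from: C0, to: C1, rate: 40.0, ligand: direct}
  - {from: C1, to: C0, rate: 0.15}
  - {from: C1, to: C2, rate: 20.0, ligand: direct}
  - {from: C2, to: C1, rate: 0.3}
  - {from: C2, to: O, rate: 2.0}
  - {from: O, to: C2, rate: 0.25}
  - {from: C2, to: D, rate: 0.6}
  - {from: D, to: C2, rate: 0.01}
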