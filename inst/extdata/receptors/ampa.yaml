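schema_version: 1
family: ampa
description: >
  Fast desensitising AMPA receptor: three closed (unbound/mono/di-liganded)
  states, one open, one desensitised. Ligand-tagged rates are per mM per ms.
states: [C0, C1, C2, O, D]
open: [O]
e_rev_mV: 0.0
q10: 2.4
t_orig_C: 30
access: {direct: 1.0, spill: 0.5}
transitions:
  - {from: C0, to: C1, rate: 10.0, ligand: direct}
  - {from: C1, to: C0, rate: 5.0}
  - {from: C1, to: C2, rate: 10.0, ligand: direct}
  - {from: C2, to: C1, rate: 6.0}
  - {from: C2, to: O, rate: 20.0}
  - {from: O, to: C2, rate: 3.0}
  - {from: C2, to: D, rate: 2.0}
  - {from: D, to: C2, rate: 0.05}
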