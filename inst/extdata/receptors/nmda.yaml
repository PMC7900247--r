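schema_version: 1
family: nmda
description: >
  Slow NMDA receptor with two glutamate binding steps, a desensitised state
  and a voltage-dependent Mg block evaluated as a sigmoidal factor on the
  open-channel current.
states: [C0, C1, C2, O, D]
open: [O]
e_rev_mV: 0.0
q10: 2.4
t_orig_C: 30
access: {direct: 1.0, spill: 1.0}
mg_block: {k_conc_mM: 3.57, k_v_per_mV: 0.04}
transitions:
  - {from: C0, to: C1, rate: 5.0, ligand: direct}
  - {from: C1, to: C0, rate: 0.0129}
  - {from: C1, to: C2, rate: 5.0, ligand: direct}
  - {from: C2, to: C1, rate: 0.0258}
  - {from: C2, to: O, rate: 0.02}
  - {from: O, to: C2, rate: 0.03}
  - {from: C2, to: D, rate: 0.0084}
  - {from: D, to: C2, rate: 0.0068}
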