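schema_version: 1
synapse: aa_goc
description: >
  Ascending-axon (GrC) to Golgi-cell synapse on basolateral dendrites:
  AMPA + NMDA only, maximal conductances about twice the parallel-fibre
  values; same release probability and vesicle cycling as pf_goc.
presyn: {p: 0.1, tau_rec_ms: 8.0, tau_facil_ms: 5.0, tau_i_ms: 1.0, delay_ms: 1.0}
transmitter:
  direct: {amp_mM: 1.0, dur_ms: 1.0}
  spill:  {amp_mM: 0.25, tau_rise_ms: 1.0, tau_decay_ms: 12.0}
receptors:
  ampa:
    scheme: ampa
    weight_nS: 1.2
    weight_scale: 1.0
    close_scale: 1.0
  nmda:
    scheme: nmda
    weight_nS: 0.5
    weight_scale: 1.0
    close_scale: 1.0
target: soma
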