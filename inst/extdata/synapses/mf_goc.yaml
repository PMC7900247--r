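schema_version: 1
synapse: mf_goc
description: >
  Glutamatergic mossy-fibre to Golgi-cell synapse (AMPA + NMDA), adapted from
  the mf-GrC synapse and calibrated to a single-pulse EPSC peak of -66 pA.
presyn: {p: 0.6, tau_rec_ms: 8.0, tau_facil_ms: 5.0, tau_i_ms: 1.0, delay_ms: 1.0}
transmitter:
  direct: {amp_mM: 1.0, dur_ms: 1.0}
  spill:  {amp_mM: 0.25, tau_rise_ms: 1.0, tau_decay_ms: 12.0}
receptors:
  ampa:
    scheme: ampa
    weight_nS: 1.75
    weight_scale: 1.0
    close_scale: 1.0
  nmda:
    scheme: nmda
    weight_nS: 0.15
    weight_scale: 1.0
    close_scale: 1.0
target: soma
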