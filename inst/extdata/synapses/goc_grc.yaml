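schema_version: 1
synapse: goc_grc
description: >
  GABAergic Golgi-cell to granule-cell synapse in the glomerulus: fast
  alpha1 and slow alpha6 GABA-A receptor schemes with glomerular spillover
  generating the transient and sustained components of inhibition.
presyn: {p: 0.35, tau_rec_ms: 36.0, tau_facil_ms: 58.5, tau_i_ms: 0.1, delay_ms: 1.0}
transmitter:
  direct: {amp_mM: 1.0, dur_ms: 1.0}
  spill:  {amp_mM: 0.25, tau_rise_ms: 2.0, tau_decay_ms: 50.0}
receptors:
  gabaa_alpha1:
    scheme: gabaa_alpha1
    weight_nS: 0.35
    weight_scale: 1.0
    close_scale: 1.0
  gabaa_alpha6:
    scheme: gabaa_alpha6
    weight_nS: 0.14
    weight_scale: 1.0
    close_scale: 1.0
target: dend
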