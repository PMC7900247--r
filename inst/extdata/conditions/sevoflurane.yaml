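schema_version: 1
condition: sevoflurane
description: >
  Full sevoflurane bundle: persistent-Na kinetic changes (A_on 0.75 -> 1.5,
  A_off 0.005 -> 0.05 ms^-1) and Na conductance increase, plus the Kv
  conductance increase (0.003 -> 0.005 S/cm2 in hillock and axon), NMDA
  removal at the mossy-fibre synapse, and the calibrated GABAergic
  potentiation at the GoC-GrC synapse (increased release probability,
  slowed alpha1 closing, enhanced alpha1/alpha6 weights).
intrinsic:
  grc.channels.nap.params.Aon: 1.5
  grc.channels.nap.params.Aoff: 0.05
  grc.channels.na.density_S_cm2.hillock: 0.04
  grc.channels.na.density_S_cm2.axon: 0.03
  grc.channels.kv.density_S_cm2.hillock: 0.005
  grc.channels.kv.density_S_cm2.axon: 0.005
synaptic:
  mf_grc.receptors.nmda.weight_scale: 0.0
  goc_grc.presyn.p: 0.52
  goc_grc.receptors.gabaa_alpha1.close_scale: 0.7
  goc_grc.receptors.gabaa_alpha1.weight_scale: 1.0
  goc_grc.receptors.gabaa_alpha6.weight_scale: 1.9
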