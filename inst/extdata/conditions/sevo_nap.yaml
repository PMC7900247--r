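schema_version: 1
condition: sevo_nap
description: >
  Sevoflurane Na-side intrinsic changes only: accelerated persistent-Na
  availability kinetics (A_on 0.75 -> 1.5, A_off 0.005 -> 0.05 ms^-1,
  raising the open-pathway availability about five-fold) plus the increased
  voltage-gated Na conductance (hillock 0.03 -> 0.04, axon 0.02 -> 0.03
  S/cm2); Kv unchanged. Reproduces the saturating spike-count difference of
  the Nap-only manipulation.
intrinsic:
  grc.channels.nap.params.Aon: 1.5
  grc.channels.nap.params.Aoff: 0.05
  grc.channels.na.density_S_cm2.hillock: 0.04
  grc.channels.na.density_S_cm2.axon: 0.03
synaptic: {}
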