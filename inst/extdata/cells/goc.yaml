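schema_version: 1
cell: goc
description: >
  Single-compartment Golgi-cell spiking surrogate: fast interneuron-type
  Na/K spiking kinetics (Wang-Buzsaki form, rate multiplier folded into the
  per-channel q10 entries) plus leak. Serves as the feedforward inhibitory
  spike source of the reduced circuit; intrinsic parameters are identical in
  control and sevoflurane bundles.
resting_potential_mV: -65
leak_reversal: fixed
capacitance_uF_cm2: 1.0
axial_resistivity_ohm_cm: 100
reversal_mV:
  na: 55.0
  k: -90.0
  leak: -65.0
density_q10: {q10: 1.5, t_orig_C: 30}
compartments:
  soma: {length_um: 13.0, diam_um: 13.0}
channels:
  na:
    type: wbna
    e_rev: na
    q10: 1
    t_orig_C: 30
    density_S_cm2: {soma: 0.035}
    params:
      Aam: -0.5
      V0am: -35.0
      Kam: -10.0
      Abm: 20.0
      V0bm: -60.0
      Kbm: -18.0
      Aah: 0.35
      V0ah: -58.0
      Kah: -20.0
      Abh: 5.0
      V0bh: -28.0
      Kbh: -10.0
  k:
    type: kv
    e_rev: k
    q10: 1
    t_orig_C: 30
    density_S_cm2: {soma: 0.009}
    params: {Aa: -0.05, V0a: -34.0, Ka: -10.0, Ab: 0.625, V0b: -44.0, Kb: -80.0}
  leak:
    type: leak
    e_rev: leak
    q10: 1.5
    t_orig_C: 30
    density_S_cm2: {soma: 1.0e-4}
    params: {dummy: 0}
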