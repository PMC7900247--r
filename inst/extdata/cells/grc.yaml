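schema_version: 1
cell: grc
description: >
  Multi-compartment cerebellar granule cell. Channel complement and kinetics
  follow the granule-cell model family (Hodgkin-Huxley-style K channels, an
  allosteric Markov Na scheme carrying transient, persistent and resurgent
  components); the baseline adaptation doubles the GABA-A leak (60 uS/cm2),
  scales the inward rectifier by 1.5x (1350 uS/cm2) and adjusts the leak
  reversal so the cell rests at -70 mV. Rates tagged t_orig_C 30 are stored
  at the 30 C simulation reference; the Na scheme is stored at its 20 C
  characterisation temperature and Q10-corrected at build time.
resting_potential_mV: -70
leak_reversal: auto
capacitance_uF_cm2: 1.0
axial_resistivity_ohm_cm: 100
reversal_mV:
  na: 87.39
  k: -84.69
  ca: 129.33
  gaba: -65.0
  leak: -58.0
density_q10: {q10: 1.5, t_orig_C: 30}
compartments:
  soma:    {length_um: 5.8,  diam_um: 5.8}
  dend:    {length_um: 15.0, diam_um: 0.75}
  hillock: {length_um: 5.0,  diam_um: 2.0}
  axon:    {length_um: 103.0, diam_um: 0.8}
ca_pool:
  compartment: soma
  ca0_mM: 1.0e-4
  beta_per_ms: 1.5
  depth_um: 0.2
channels:
  na:
    type: na_allo
    e_rev: na
    q10: 3
    t_orig_C: 20
    density_S_cm2: {hillock: 0.03, axon: 0.02}
    params:
      Aalfa: 353.91
      Valfa: 13.99
      Abeta: 1.35
      Vbeta: 13.99
      Agamma: 300.0
      Adelta: 30.0
      Aepsilon: 1.75
      Ateta: 0.0201
      Vteta: 25.0
      ACon: 0.001
      ACoff: 0.5
      AOon: 0.5
      AOoff: 0.005
      n1: 5.422
      n2: 3.279
      n3: 1.83
      n4: 0.738
  nap:
    type: nap
    e_rev: na
    q10: 3
    t_orig_C: 30
    density_S_cm2: {hillock: 0.0, axon: 0.004}
    params: {V0m: -36.0, Km: -5.0, tau_m: 5.0, Aon: 0.75, Aoff: 0.005}
  kv:
    type: kv
    e_rev: k
    q10: 3
    t_orig_C: 30
    density_S_cm2: {hillock: 0.003, axon: 0.003}
    params: {Aa: -0.06, V0a: -25.0, Ka: -10.0, Ab: 0.15, V0b: -35.0, Kb: -80.0}
  ka:
    type: ka
    e_rev: k
    q10: 3
    t_orig_C: 30
    density_S_cm2: {soma: 0.006}
    params:
      Aaa: 2.44
      V0aa: -9.17
      Kaa: -23.32
      Aba: 0.497
      V0ba: -18.28
      Kba: 19.47
      Aab: 0.11
      V0ab: -111.33
      Kab: 12.8
      Abb: 0.103
      V0bb: -49.9
      Kbb: -8.9
  kir:
    type: kir
    e_rev: k
    q10: 3
    t_orig_C: 30
    density_S_cm2: {soma: 0.00135}
    params: {Aa: 0.399, V0a: -83.94, Ka: -24.3902, Ab: 0.51, V0b: -83.94, Kb: 35.714}
  kca:
    type: kca
    e_rev: k
    q10: 3
    t_orig_C: 30
    density_S_cm2: {soma: 0.03}
    params: {Aa: 7.5, Ba: 0.0015, Ka: 0.085, Ab: 4.5, Bb: 0.00015, Kb: 0.077}
  ca:
    type: cahva
    e_rev: ca
    q10: 3
    t_orig_C: 30
    density_S_cm2: {soma: 0.0015}
    params:
      Aas: 0.148
      V0as: -29.06
      Kas: 15.873
      Abs: 0.249
      V0bs: -18.66
      Kbs: -25.641
      Aau: 0.0039
      V0au: -48.0
      Kau: -18.183
      Abu: 0.0039
      V0bu: -48.0
      Kbu: 83.33
  km:
    type: km
    e_rev: k
    q10: 3
    t_orig_C: 30
    density_S_cm2: {soma: 0.005}
    params: {Aa: 0.06, V0a: -30.0, Ka: 40.0, Ab: 0.06, V0b: -30.0, Kb: -20.0, V0inf: -40.0, Kinf: -6.0}
  gaba_leak:
    type: leak
    e_rev: gaba
    q10: 1.5
    t_orig_C: 30
    density_S_cm2: {soma: 6.0e-5, dend: 6.0e-5}
    params: {dummy: 0}
  leak:
    type: leak
    e_rev: leak
    q10: 1.5
    t_orig_C: 30
    density_S_cm2: {soma: 5.68e-5, dend: 5.68e-5, hillock: 5.68e-5, axon: 5.68e-5}
    params: {dummy: 0}
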