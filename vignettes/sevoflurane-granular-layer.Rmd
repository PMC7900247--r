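---
title: "Modelling sevoflurane action at the cerebellar input stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sevoflurane action at the cerebellar input stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Sevoflurane, a halogenated general anesthetic, changes neuronal communication
at the input stage of the cerebellum in three ways at once: it potentiates
GABAergic inhibition at the Golgi-cell (GoC) to granule-cell (GrC) synapse,
it abolishes the NMDA component of mossy-fibre (mf) excitation, and —
counter-intuitively — it *increases* the intrinsic excitability of the
granule cell, lowering its firing threshold and rheobase. This package
implements a conductance-based model of that system: a multi-compartment GrC,
a spiking GoC surrogate, kinetic-scheme synapses with glomerular spillover,
and the stimulation protocols needed to compare a `"control"` parameter
bundle against a `"sevoflurane"` bundle that encodes the three actions.

Everything is organised around *condition bundles*: auditable YAML diffs
against the control parameter files (`condition_set("sevoflurane")` prints
every override). The simulations themselves are deterministic; a seed is
only needed for the synthetic ground-truth generators.

# The granule-cell model

The GrC has seven compartments — soma, four dendrites, axon hillock and an
ascending-axon section — coupled by axial conductances (about 3 pF total
capacitance and a GΩ-range input resistance, as measured in these cells).
The channel complement follows the granule-cell model family:

* **Transient Na** (hillock + axon): a 13-state allosteric Markov scheme
  (five closed, open, open-blocked, six inactivated states) carrying the
  transient and resurgent components. Densities are 0.03 S/cm² (hillock) and
  0.02 S/cm² (axon) in control.
* **Persistent Na (Nap)** (axon): a separate channel, `g · m · h`, with fast
  activation (half-activation −40 mV, slope 5 mV, τ ≈ 5 ms) and a slow,
  voltage-independent availability gate whose on/off rates are the
  condition-controlled parameters `A_on` and `A_off`. In control
  (`A_on = 0.75`, `A_off = 0.005` ms⁻¹) the open-pathway availability is
  `A_off/(A_on+A_off)` ≈ 0.7%; the sevoflurane values (1.5, 0.05 ms⁻¹)
  raise it to ≈ 3.2% — a five-fold increase of the persistent current at
  all subthreshold potentials — while accelerating both transitions.
* **Kv delayed rectifier** (hillock + axon, 0.003 S/cm² control), **KA**,
  **inward rectifier Kir** (1350 µS/cm², the 1.5×-scaled baseline
  adaptation), **Ca (HVA)** with a submembrane Ca pool, **KCa**, and a slow
  K current, all somatic; leak plus a GABA-A leak (60 µS/cm², the 2×-scaled
  baseline) on soma and dendrites. The leak reversal is adjusted
  automatically at build time (secant iteration on short simulations) so the
  cell rests at −70 mV, mirroring the published adaptation.

**Why a separate Nap channel.** The printed kinetic values coincide with the
open-state inactivation constants of the allosteric Na scheme, and that
reading was implemented first. Measured on the scheme, however, changing
those two rates leaves the steady persistent open fraction essentially
unchanged below −50 mV, so the anesthetic bundle barely moves the threshold.
Interpreting `A_on`/`A_off` as the kinetic scale parameters of a dedicated
persistent-Na gating scheme — activation unchanged, availability set by the
two rates — both accelerates the kinetics and scales the standing persistent
current, which is what the threshold and rheobase phenomenology requires.

**Temperature.** All rates carry a Q10 class (`q10_factor()`): 3 for ionic
gating, 2.4 for receptor gating, 1.5 for permeation, 1.3 for transmitter
diffusion, 3 for Ca pumps/buffers (the intracellular-Ca-diffusion class is
recorded with both the 1.3 and 1.7 variants but is not exercised by the
reduced Ca pool). Parameter files state each channel's reference
temperature; most kinetics are stored at the 30 °C simulation reference
(already adapted), the allosteric Na scheme at its 20 °C characterisation
temperature. Simulations default to 30 °C, the recording-chamber
temperature the protocols emulate.

# The Golgi-cell surrogate

Circuit protocols need the GoC only as a feedforward spike source with a
realistic relay latency and a calibrated mossy-fibre synapse. The package
therefore uses a single-compartment fast-spiking interneuron model
(Wang–Buzsáki Na/K kinetics plus leak, ~1.3 pF) rather than a full
multi-compartment GoC: it converts a mossy-fibre volley into spikes about
2 ms after the stimulus, and its mf synapse is calibrated to the −66 pA
single-pulse EPSC. Its intrinsic parameters are identical in both
conditions, as no GoC-intrinsic anesthetic action is modelled.

# Synapses

All five synapse classes share one architecture: a deterministic
Tsodyks–Markram-type presynaptic recursion with three vesicle pools
(recovered → effective → inactive → recovered, time constants `tau_i` and
`tau_rec`) and a facilitation variable that jumps by `p·(1−u)` at each
spike — so an isolated spike releases exactly `p`; a transmitter time course
with a 1 ms cleft pulse plus a slower biexponential glomerular spillover
component; and one or more multi-state receptor schemes (AMPA, NMDA,
GABA-A α1, GABA-A α6, kainate) whose occupancies are integrated as
conservative Markov systems. The printed presynaptic bundles are used
verbatim (mf→GrC: p 0.6, τ_rec 8 ms, τ_facil 5 ms, τ_I 1 ms; GoC→GrC:
p 0.35, 36, 58.5, 0.1 ms; PF→GoC p 0.1; 1 ms delay everywhere).

Receptor rate constants are not printed in the source material; they are
encoded from the standard kinetic-scheme literature and calibrated once:
the NMDA scheme opens slowly so an isolated 4×100 Hz burst sums to a peak
≈ 20 ms after the last stimulus, and its Mg block is a two-parameter
sigmoid with weak voltage sensitivity (0.04 /mV), consistent with the
NR2C-type receptors of granule cells; the GABA-A α1 scheme produces the
fast IPSC (decay ≈ 16 ms at 30 °C), the high-affinity α6 scheme the
spillover-driven sustained component unmasked by repetitive stimulation.

**The sevoflurane GABA bundle.** The supplementary table with the original
synaptic values is not part of the available text, so the bundle is
implemented as four free scale factors — release probability 0.35 → 0.52,
α1 closing ×0.7, α1 weight ×1.0, α6 weight ×1.9 — calibrated *once* against
the experimental percent-change bands for the evoked IPSC (peak
+47.6 ± 7.1%, decay τ +43.8 ± 6.5%, paired-pulse ratio −12.7 ± 2.3%) and
then frozen in the condition file. The model's own single-stimulus IPSC
percent changes (the quantities `scripts/acceptance.R` recomputes) follow
from this calibration; they are not assigned anywhere.

# Protocols

* `run_current_steps()` — intrinsic excitability: the cell is biased to
  −60 mV (the experimental resting potential for these measurements; the
  bias is found by voltage clamp) and 500 ms steps of 1–16 pA are injected
  on top. `fi_table()` and `rheobase()` derive counts, frequencies and the
  dV/dt-criterion threshold (20 mV/ms, configurable).
* `run_epsc_burst()`, `run_nmda_isolation()`, `run_ipsc_protocol()` —
  voltage-clamp synaptic protocols, implemented at receptor level under an
  ideal somatic clamp of the electrotonically compact GrC.
* `run_epsp_protocol()` — current clamp near −60 mV; the no-inhibition
  configuration activates a single mossy fibre, the inhibition-active one
  three fibres and one GoC, as in the modelled EPSP comparison.
* `run_pp_frequency_sweep()` — pairs of mf action potentials at 10–200 Hz
  through the reduced circuit (1–4 mf × 0–7 GoC); output frequency is
  spikes in a fixed 100 ms response window (a documented, configurable
  convention, since the source defines none); a response without spikes is
  scored as maximally delayed in delay comparisons.
* A *stimulation intensity* argument scales the mf→GrC weights, mirroring
  the experimental adjustment of stimulus strength (sub-threshold for EPSP
  recordings, intensity 0.6; just-suprathreshold for spike protocols,
  intensity 0.9). Golgi-cell recruitment is treated as all-or-none.
* `reproduce()` bundles the condition-compared protocols behind the four
  modelled figures and returns a pass/fail table against the published
  simulation values at the package tolerances.

Because all afferents of a class are deterministic and identical, multiple
fibres/GoCs are folded into synapse multiplicities (a pure weight scaling),
which keeps the full E/I sweep inexpensive.

# Numerics

Fixed-step integration at dt = 0.025 ms: Crank–Nicolson for the coupled
compartment voltages, exponential Euler for Hodgkin–Huxley gates, backward
Euler for Markov schemes (which conserves occupancy exactly and preserves
positivity — the receptor and Na-scheme occupancies stay normalised to
1e−9 and better). Voltage clamp is an ideal space clamp. Spike-time
convergence under dt halving is first order: the first spike moves by well
under 0.1 ms, while phase drift accumulates along a long train (~60 µs per
spike); the convergence test therefore checks count identity, first-spike
timing and total drift below one interspike interval. The implicit receptor
step slightly damps the sharpest open-probability peaks (a few percent on
the fast α1 transient, checked against an adaptive-solver reference);
both conditions share the bias, so percent-change comparisons are
unaffected.

# Synthetic ground truth

`gen_psc_train()`, `gen_spike_trace()` and `stochastic_release_oracle()`
exist so that every analysis operator is testable without the biophysical
core: biexponential events with closed-form peak, rise and charge; spike
templates whose upstroke crosses the dV/dt criterion at a constructed
voltage; and an exact continuous-time Monte-Carlo counterpart of the
release recursion. The generators emulate event kinetics and white Gaussian
noise only — no series-resistance artifacts, line noise or electrode
filtering — so passing recovery tests demonstrates correctness of the
operators, not robustness to every feature of real recordings.

# Design choices and limitations

* The GrC morphology (soma 5.8 µm, four 15 µm dendrites, hillock, ~100 µm
  axon section) and all non-printed kinetics were calibrated once so the
  control model reproduces the published control behaviour (rest −70 mV,
  threshold ≈ −47 mV, rheobase in the 6 pA range, tonic f-I up to ~100 Hz)
  and then frozen; the condition bundles only apply the printed changes.
* The sevoflurane threshold shift is reproduced in direction but not in
  full magnitude: configurations strong enough to read −54.8 mV at the
  somatic dV/dt criterion drive the model into depolarisation block. The
  model's reading sits ~1–1.5 mV below control.
* In the reduced circuit the sevoflurane condition is more excitable at
  zero inhibition (anticipated first spike) and strongly suppressed once
  any GoC is active; the suppression is closer to all-or-none than the
  graded prolongation of the source system, and the control I/O curve is
  non-monotone in input frequency, so the slope comparison is not a robust
  feature of this reduction.
* No quantal/stochastic release in production runs (the Monte-Carlo oracle
  is test-only), no GABA-B, no tonic GABA-A beyond the fixed GABA leak, no
  plasticity, and no network-scale simulations.
* Trace containers are full-precision CSV (bit-identical round trips) plus
  a YAML run manifest whose recorded call and parameter-file checksums
  reproduce any run bit-identically (`rerun_manifest()`).
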