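---
title: "A six-layer thalamocortical model of slow oscillations and sleep spindles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A six-layer thalamocortical model of slow oscillations and sleep spindles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spindlenet` simulates a conductance-based network of six one-dimensional
cell layers: 200 cortical pyramidal cells (PY) and 40 interneurons (IN) on
top, and two independent thalamic relay/reticular pairs of 40 cells each
below — a "fast" pair (TC_f/RE_f) that generates 12–16 Hz spindles and a
"slow" pair (TC_s/RE_s), held at a more hyperpolarized working point, that
generates 8–12 Hz spindles. The cortical layers produce a ~1 Hz NREM slow
oscillation (SO): hyperpolarized *down* states in which the population is
silent alternate with depolarized *up* states of collective firing.

Cortical cells are two-compartment: a dendritic compartment carrying the
leak, persistent sodium (I_Nap), slow potassium (I_Km), calcium-dependent
potassium (I_KCa) and high-threshold calcium (I_HVA) currents, coupled to a
quasi-static axosomatic compartment carrying the spike currents (I_Na,
I_K, plus somatic I_Nap in PY). The somatic membrane equation is an
algebraic constraint — zero net somatic current through the coupling
conductance `g_DS = 1/(R S_soma)` with `R = 10` MΩ and
`S_soma = 1e-6` cm²; the dendrite-to-soma area ratio is ρ = 165 (PY) or
50 (IN). Thalamic cells are single-compartment with I_Na, I_K, the
potassium leak I_KL, the low-threshold calcium current I_T, and (relay
cells only) the hyperpolarization-activated cation current I_h with a
two-state open/closed scheme. Intracellular calcium follows a linear pool,
`d[Ca]/dt = -A·I_Ca + ([Ca]_inf - [Ca])/τ`.

Synapses are first-order kinetic schemes (AMPA, NMDA, GABA-A): a
presynaptic spike deposits a rectangular transmitter pulse (amplitude 0.5,
duration `t_max`) that drives `dO/dt = α(1-O)T - βO`; the current is
`g·D·O·f(V)(V - E)` with the NMDA sigmoid gate
`f(V) = 1/(1+exp(-(V+25)/12.5))` and short-term depression `D` on the
intracortical AMPA and GABA-A pathways
(`D ← 1 - (1 - D(1-U))e^{-Δt/700 ms}`, `U = 0.07/0.073`). GABA-B uses a
second-order G-protein cascade (`R`, `G`) with a fourth-power Hill
activation of a potassium conductance. Connectivity is radius-based along
the chains, with the 200:40 layers mapped proportionally onto each other;
the corticothalamic projections to the slow pair carry a 600 ms conduction
delay, which is what places slow-spindle feedback in the second half of the
SO cycle.

SO cycles are initiated by miniature synaptic currents: Poisson-timed
small AMPA/GABA-A events on the intracortical pathways that switch on
~100 ms after a down state begins and switch off once the next cycle
ignites. Their temporal summation depolarizes a few PY cells to threshold;
recurrent excitation recruits the layer; accumulating dendritic calcium
(through I_KCa) and synaptic depression terminate the up state.

## Parameters that matter

* **Integration**: exponential Euler for gating and synaptic states (all
  voltage-dependent steady states and per-step decay factors are
  pre-tabulated on a 0.05 mV grid), a conductance-implicit update for the
  membrane potentials, and a damped-Newton solve (tolerance 1e-6 mV) of
  the somatic constraint each step. Fixed step `dt = 0.025` ms by default;
  halving or doubling the step changes isolated-network rhythm frequencies
  by well under 2% (tested).
* **Transmitter pulse** `t_max = 0.3` ms. The alternative 0.03 ms reading
  is available in the config; with it, single-spike open-fraction
  increments are ~10× smaller and the intracortical recurrence cannot
  sustain up states.
* **Miniature currents** (calibrated, config-exposed): rate 60 Hz per
  target synapse while gated on; amplitudes 0.0375 µS (PY–PY), 0.01 µS
  (PY–IN), 0.03 µS (IN–PY). These were chosen once so that the isolated
  two-layer cortical network cycles at ~1.3 Hz; the reduced-mini protocol
  multiplies the rate by 0.8.
* **Conductance-table semantics**: synaptic conductances are per-synapse
  values except the intracortical PY→IN and IN→PY rows, which are read as
  per-target totals divided across the fan-in (their magnitudes — 0.05 and
  0.16 µS — are total-scale, and a 160 nS unitary inhibitory conductance
  on a 5e-5 cm² dendrite would silence the layer). The `per_target` column
  of `projection_table()` records the reading per row and both
  interpretations are switchable.
* **Thalamic GABA-A reversals**: −85 mV onto fast relay cells (the
  standard relay-cell value in this model family; reticular inhibition
  must hyperpolarize TC below rest for I_T to deinactivate), −88 mV onto
  slow relay cells, −70 mV elsewhere.
* **T current**: relay cells use the canonical relay T-current gating
  (activation midpoint −59 mV, slope 6.2; inactivation −83 mV, slope 4,
  after a +2 mV screening shift; Q10-corrected to 36 °C) with exponent
  M = 2 and a GHK driving function normalized to the ohmic drive at
  −60 mV. Reticular cells use the standard reticular T-current forms with
  their printed temperature factors. The fast pair's higher `g_T` (1.8 vs
  1.0 mS/cm²) and less hyperpolarized leak are what make it oscillate at
  14–16 Hz rather than 8–10 Hz.
* **Cortical calcium/KCa**: the dendritic calcium pool relaxes with
  τ = 165 ms (thalamic pools: 5 ms) and the KCa activation rate is read as
  0.01 per µM of calcium. Both choices are what let I_KCa accumulate over
  an up state and terminate it; with a 5 ms pool or a per-mM rate the
  current never activates and dendrites latch into a depolarized plateau.
* **Heterogeneity**: each cortical cell's dendritic leak conductance is
  jittered uniformly by ±10% (seed-controlled). Identical cells lock into
  all-or-none population volleys; the jitter breaks the symmetry.
  Thalamic layers are left homogeneous.
* **State machine**: an up state begins when the PY population rate
  exceeds 10 Hz/cell in a 20 ms window and ends after 300 ms below
  1 Hz/cell. The long hold is deliberate: up states in this model are
  trains of population discharges ~100 ms apart, and a short hold would
  split one up state into many and re-open the mini gate inside it.
* **LFP**: the sum of AMPA, NMDA and GABA-A presynaptic currents onto PY
  cells, sampled at 1 kHz, sign-flipped (up states plot upward) and
  multiplied by a global display scale of 0.324, calibrated once on the
  control condition so that mean SO amplitudes fall in the 8 mV range.
  Smoothing is a causal 200-sample moving average.

## Protocols and presets

`protocol_minis()` drives the default SO regime. `protocol_step()`
reproduces the isolated-network experiments: 0.065 nA into every TC cell
and 0.09 nA into every RE cell for 600 ms every 3 s. The presets in
`preset()` assemble the manipulation experiments as pure overrides of the
control configuration: blocking either or both thalamic pairs (zeroing the
corticothalamic conductances), reducing minis, raising the fast relay
potassium leak from 0.03 to 0.033 mS/cm², swapping the slow pair's
parameters for the fast pair's, and the three isolated-subnetwork runs.

## Analysis pipeline

`compute_lfp()` → `smooth_lfp()` → `power_spectrum()` (Welch,
Hann-windowed) / `spectrogram()` (1 s window, 90% overlap);
`segment_so_cycles()` segments cycles from the PY population rate and
labels a cycle as slow-spindle-initiated when slow-relay spikes precede
the up onset within 200 ms and no miniature event fell in the preceding
100 ms; `detect_events()` groups thalamic population spikes into events
separated by >250 ms silence and applies the ≥0.5 s proper-spindle rule;
`cell_events()` does the same for a single cell; `summary_statistics()`
collects the per-condition report and `compare_conditions()` reports
Welch tests (P < .01 criterion) alongside Cohen's d.

Two frequency readouts are provided for the step-protocol runs:
`isi_dominant_frequency()` (the modal inverse inter-spike interval of one
cell) and `membrane_dominant_frequency()` (the spectral peak of the same
cell's membrane potential within the stimulation windows). The second is
the reported one: relay cells often fire on every second cycle of a
spindle while their membrane potential oscillates at the full network
frequency, so the ISI mode can read near half the rhythm.

## Problem sizes

Test-suite runs use 12 s isolated-network and 40 s full-network spans with
one seed; the acceptance script uses 12 s, 45 s and 50 s spans with two
seeds for the control and cortex conditions. Down-state totals defined
over 120 s are rescaled linearly to that basis.

## What the synthetic regime does and does not show

The generator reproduces the study's own conditions — fully synthetic
drive, uniform printed conductances, no channel noise — so passing tests
demonstrate internal consistency of the model, not fidelity to recorded
sleep EEG. Known limitations of this implementation, visible in its
numbers:

* Cortical up states are shorter than the few-hundred-millisecond-to-
  second depolarizations the mechanism aims for: ignition and termination
  work, but the recurrent/adaptation balance holds collective firing for
  ~100–300 ms, so the fraction of time spent in down states is high and
  total down-state times are correspondingly large.
* The fast spindle loop saturates near 14–15 Hz rather than 16 Hz under
  the step protocol, and the potassium-leak manipulation shifts it by a
  few tenths of a hertz rather than ~2 Hz.
* Slow relay cells fire seldom (as intended), but too seldom to initiate
  an appreciable fraction of SO cycles, so the slow-spindle-initiation
  fraction and the down-state-time contrast between the reduced-mini
  conditions are much weaker than targeted.
* Fast spindles never wane spontaneously: with the printed G-protein
  constants the GABA-B Hill activation needs a near-saturated receptor
  fraction, so there is no slow negative feedback inside a spindle, and a
  kicked fast pair keeps oscillating until its drive changes.
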