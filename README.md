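# spindlenet

A conductance-based thalamocortical network model of NREM sleep for R.
The package is aimed at computational neuroscientists studying how
cortical slow oscillations (SO, ~1 Hz) interact with the two classes of
human sleep spindles: fast spindles (12–16 Hz), which nest at the SO
down-to-up transition, and slow spindles (8–12 Hz), which nest at the
up-to-down transition.

## The model

Six one-dimensional cell layers: 200 two-compartment pyramidal cells (PY)
and 40 interneurons (IN) form the cortex; two independent relay/reticular
pairs of 40 Hodgkin–Huxley cells each (TC_f/RE_f and TC_s/RE_s) form a
fast and a slow thalamic subnetwork, the slow pair held at a more
hyperpolarized working point (GABA-A reversal −88 mV onto its relay cells,
leak reversals −77/−82 mV) and coupled to cortex with a 600 ms conduction
delay. Cortical membrane dynamics follow

```
C_m dV_D/dt = −g_L(V_D−E_L) − g_SD(V_D−V_S) − I_D^int − I_syn
          0 = −g_DS(V_S−V_D) − I_S^int
```

with intrinsic currents I_Na, I_K, I_Nap, I_Km, I_KCa, I_HVA and leaks;
thalamic cells are single-compartment with I_Na, I_K, I_KL, I_T (GHK
driving force) and, in relay cells, I_h. Synapses are first-order
AMPA/NMDA/GABA-A kinetics with short-term depression on the intracortical
pathways, plus a second-order GABA-B G-protein cascade
(`I = g G⁴/(G⁴+K)(V−E_K)`). SO cycles are ignited by Poisson miniature
synaptic currents that are gated on ~100 ms after each down-state onset
and off at the next cycle's ignition; the reciprocal TC–RE loops convert
cortical drive into spindle oscillations that feed back to cortex.

The fixed-step network integrator is written in C++ (exponential-Euler
gating with tabulated kinetics, conductance-implicit voltage updates,
per-step Newton solve of the axosomatic constraint); everything else —
configuration, protocols, manipulations, LFP/spectral/event analysis — is
tibble-first R.

## A worked example

```r
library(spindlenet)

# isolated fast thalamic subnetwork under the step protocol
# (0.065 nA to TC, 0.09 nA to RE, 600 ms on every 3 s)
r <- run_preset("fast_isolated", seed = 1)
r$report
#> # A tibble: 1 × 3
#>   tc_dominant_hz tc_isi_hz n_spikes
#>            <dbl>     <dbl>    <int>
#> 1           14.2      7.25     5910
```

`tc_dominant_hz` is the spindle frequency read from the central relay
cell's membrane-potential spectrum inside the stimulation windows — here
a ~14.2 Hz fast-spindle rhythm. `tc_isi_hz` is the modal inverse
inter-spike interval of the same cell; it reads near half the rhythm
because the cell fires on every second cycle.

```r
# full six-layer control network, mini-driven slow oscillations
ctrl <- run_preset("control_full", seed = 1, duration_ms = 30000)
dplyr::select(ctrl$report, n_cycles, so_rate_hz, so_amplitude_mean,
              slow_events_per_min)
#> # A tibble: 1 × 4
#>   n_cycles so_rate_hz so_amplitude_mean slow_events_per_min
#>      <int>      <dbl>             <dbl>               <dbl>
#> 1       38       1.29              8.15                26.4
```

Thirty seconds of the control network produce 38 slow-oscillation cycles
(~1.3 Hz) with a mean cycle amplitude of ~8 mV on the scaled LFP axis and
~26 slow-subnetwork events per minute. `autoplot(ctrl$sim)` draws the
spike raster; `compute_lfp()`, `power_spectrum()` and `spectrogram()`
expose the field-potential view, and `segment_so_cycles()` /
`detect_events()` the cycle- and event-level statistics.

Manipulations are pure operations on a network object:

```r
net <- build_network(network_config())
net |> block_subnetwork("slow")            # silence slow spindles
net |> apply_gkl_override("TC_f", 0.033)   # hyperpolarize the fast pair
net |> swap_slow_for_fast()                # fast spindles in both SO halves
```

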