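---
title: "A conductance-based model of the HVC premotor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A conductance-based model of the HVC premotor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hvcnet` simulates the zebra finch premotor nucleus HVC as a small
biophysical network: tonically firing inhibitory interneurons, sparsely
bursting excitatory projection neurons (HVC_RA), a neuromodulatory
trigger pulse from the midbrain A11 cell group that gates motif onset,
and a feedforward excitatory chain along which the burst pattern
propagates. This vignette is the package's account of the model itself:
its equations and assumptions, the parameters that matter, the numerical
choices, and — importantly — what the implementation does and does not
reproduce of its reference behavior.

## The single-neuron models

Both cell classes are single-compartment Hodgkin–Huxley neurons in the
unit system mV / ms / pA / pF / nS / µM, chosen so that `nS·mV = pA` and
`pA/pF = mV/ms` and every tabulated value can be used verbatim. All
currents are written depolarizing-positive, `I = g·gates·(E − V)`, and
summed with `+` in the membrane equation.

The projection neuron carries `I_Na = g_Na m³h (E_Na − V)`,
`I_K = g_K n⁴ (E_K − V)` and a leak; its capacitance is 10 pF and its
leak time constant `C/g_L = 10/3 ms`. The interneuron shares the `m, h,
n` kinetics and the reversal potentials but has larger `g_Na` (1200 nS)
and `g_K` (200 nS), plus two slower currents that shape its rich firing:
a T-type calcium current `I_CaT = g_CaT a³b³·GHK(V, [Ca])` and a
hyperpolarization-activated current `I_H = g_H H² (E_H − V)`. Every gate
relaxes as `dG/dt = (η(V) − G)/τ(V)` with a tanh steady state and a
bell-shaped time constant; the `H` gate is the one gate whose steady
state and time constant use different slopes (−10 and −5.5 mV).

The calcium channel uses the Goldman–Hodgkin–Katz flux factor rather
than a linear driving force,

```
GHK(V, Ca) = V (Ca_ext e^{-ZFV/RT} - Ca) / (1 - e^{-ZFV/RT}),
```

with concentrations entered numerically in µM so that `g_CaT` (nS) times
the gate product times the factor is treated as a current in pA — this
keeps the calcium bookkeeping `d[Ca]/dt = φ I_CaT + ([Ca]₀ − [Ca])/τ_Ca`
dimensionally consistent with `φ` in µM·ms⁻¹·pA⁻¹. The factor has a
removable singularity at `V = 0`; for `|ZFV/RT| < 1e−4` a second-order
series branch is used (agreement with direct evaluation is better than
1e−6 relative at the branch point, and the tests assert continuity).

## Synapses and the trigger pulse

Chemical transmission is deliberately minimal. The cleft transmitter
concentration is an instantaneous sigmoid of presynaptic voltage
(`T_max = 2.84 mM`, half-activation +2 mV, steepness 5 mV), so
transmitter is effectively released only during spikes. Postsynaptic
receptors follow first-order kinetics `dr/dt = α[T](1 − r) − βr`
(AMPA: α = 1.1 /(mM·ms), β = 0.19 /ms, E = 0 mV; GABA_A: α = 5, β =
0.18, E = −80 mV), and the synaptic current is
`I = g_max r (E_rev − V_post)`.

One sign convention deserves a note: with ionic currents written
depolarizing-positive, the synaptic current must be written
`g r (E_rev − V_post)` — not `g r (V − E)` — for AMPA to excite and
GABA_A to inhibit when everything is summed with `+`. The implementation
adopts the former throughout; the tests pin the signs (AMPA positive
below 0 mV, GABA_A negative above −80 mV).

The A11 trigger is a transmitter pulse with baseline `T_min = 0.001 mM`,
exponential rise (`τ_r = 1.2 ms`) to the 2.84 mM peak, and exponential
decay (`τ_f = 1.2 ms`). Requiring continuity at the rise/fall transition
fixes both the transition time `t_trans = τ_r ln(T_peak/T_min) ≈
9.54 ms` and the decay branch
`(T_peak − T_min) e^{−(t − t_on − t_trans)/τ_f} + T_min`, which attains
the peak exactly and returns to baseline. Because `t_trans` depends only
logarithmically on `T_min`, scaling the baseline tenfold shifts the peak
time by `τ_r ln 10 ≈ 2.76 ms` but leaves the peak height and the ~5.5 ms
width (at 10% of peak) essentially unchanged — `sweep_tmin()` measures
exactly this. The trigger enters the network as a GABA_A synapse onto
the interneuron whose drive is the pulse concentration instead of a
presynaptic voltage; its receptor pool starts at the steady state of the
baseline concentration (the natural pre-song condition).

## Networks

`build_microcircuit()` wires A11 → interneuron (GABA_A, 8 nS) and
interneuron → projection neuron (GABA_A, 8 nS), optionally closing the
loop with projection neuron → interneuron (AMPA, 7 nS). The projection
neuron receives a 300 pA background; tonic interneuron inhibition keeps
it silent until the trigger pauses the interneuron. In the bidirectional
variant the projection neuron's own feedback re-excites the interneuron
while the pulse is still decaying, truncating the burst; removing the
feedback lets the burst run on for tens of milliseconds — the circuit's
central qualitative result.

`build_chain_network()` appends `n_ra` projection neurons: the first one
sits in the bidirectional microcircuit, and each cell excites the next
through AMPA. The first edge defaults to 10 nS (the first burst is
weaker than a full one and needs the boost); later edges default to
8.2 nS. Downstream cells receive only 50 pA of background — a deliberate
stand-in for the net inhibitory tone that keeps them subthreshold until
the burst arrives; no other inhibition reaches the chain.

### The interneuron background current

The one background current with no reference value is the
interneuron's. It matters more than any other free choice, for a reason
worth documenting: the interneuron model is *bistable* over a wide
current range. Alongside the tonic-firing limit cycle there is a stable
depolarized non-spiking state near −38 mV (sodium largely inactivated,
potassium partially engaged), and when inhibition decays away gradually
the cell slides onto that silent branch and stays there. Below ~135 pA
the cell cannot fire at all once the baseline A11 drive (~9 pA) is
subtracted; between ~135 and ~240 pA it fires from rest but never
recovers after an inhibitory pulse. The package therefore defaults to
**250 pA**, the smallest round current at which the triggered-interneuron
experiment (`generate_fixture("fig3")`) shows the required
firing → pause → resumed-firing sequence. The value was fixed on that
qualitative criterion alone and is exposed as `i_bg_int` in every
builder.

## Numerics

* **Integrator.** Classical fixed-step 4th-order Runge–Kutta over the
  full coupled state, with synaptic and trigger drives evaluated at the
  substage times. The default step is 0.02 ms; the fastest time constant
  in the model (`τ_m = 0.01 ms`) puts this near the stability edge but
  well inside it, and `check_convergence()` (step halving) plus an
  adaptive-solver cross-check in the tests confirm the traces are
  step-size converged: spike counts are dt-invariant in every regular
  regime and matched spike times agree with a `lsoda` reference at
  tolerance 1e−10 to better than 0.1 ms.
* **Initial conditions and warm-up.** Runs start from V at the leak
  reversal, gates at steady state, calcium at rest, receptor pools at
  the steady state of their resting drive. Because that instant is not
  the network's operating state (the interneuron has not yet begun
  firing), every network fixture adds a 50 ms warm-up (`settle`) before
  time zero and defers the trigger accordingly; 50 ms is ~15 membrane
  time constants and was fixed a priori. Without it the projection
  neuron fires a spurious spike in the first ~2 ms.
* **Gates are never clamped.** Boundedness of gates and receptor
  fractions in [0, 1] is a property of the dynamics; the integrator
  records the extremes seen in a run (`gate_range`, `r_range`) and the
  tests assert them, so an integration error would surface rather than
  be masked.
* **Degenerate inputs.** Non-finite states abort with the first
  offending variable and time named; zero-duration runs return the
  initial state; invalid rheobase brackets and malformed configs are
  rejected with specific messages.
* **Spike and burst conventions.** A spike is an upward crossing of
  0 mV (reported at the following voltage peak) with a 1 ms guard;
  bursts are maximal runs of interspike intervals below 15 ms; burst
  duration is last-peak minus first-peak. These conventions are
  declared rather than derived — reported durations and counts are
  meaningful only relative to them. A "full spike" means a peak above
  0 mV; local maxima between −20 and 0 mV count as miniature peaks, not
  spikes.
* **Problem sizes.** The tests and the acceptance script run the
  50-neuron chain for 200 ms (12 500 steps of 260 state variables after
  a 50 ms warm-up), the microcircuit for 120 ms, and rheobase probes for
  500 ms; a full suite run completes in a few minutes on one core.

## What the fixtures emulate — and what they do not

The fixture catalogue (`generate_fixture()`) reconstructs the model's
reference experiments: isolated cells under current steps, the triggered
interneuron, both microcircuit variants, the 50-neuron chain, the
trigger-baseline sweep, and the conductance-robustness studies
(including the randomized per-edge chain, whose uniform draws in
[8.1, 8.3] nS flow from a single recorded seed). All of them are
noise-free, point-neuron, delay-free idealizations: no HVC_X population,
no short-term plasticity, no conduction delays, no channel stochasticity
or background synaptic noise, and the "general inhibitory tone" on chain
neurons is a reduced DC background rather than modeled synapses. Passing
tests therefore certify the deterministic dynamics of this idealized
circuit, not the variability structure of in vivo recordings.

## Known limitations and measured deviations

With every tabulated parameter implemented verbatim and the integration
verified as converged, the package reproduces the reference behavior
qualitatively everywhere — tonic interneuron firing interrupted by the
trigger; a single projection-neuron burst only in the bidirectional
circuit; strictly longer bursts without the feedback loop; sequential
single bursts along the chain; three propagation regimes (extinction /
faithful copy / growth) as the chain coupling is lowered or raised — but
two quantitative features come out shifted, and the acceptance checks
report them honestly as failures rather than paper over them:

* **The projection neuron bursts faster than its reference.** The
  intra-burst interspike interval is ~1.6 ms, so the canonical 4-spike
  burst spans ~4.9 ms rather than ~8 ms (the acceptance script's `t4`).
  The burst's spike count is also sensitive to the interneuron's tonic
  phase at trigger onset (4–8 spikes across warm-up lengths; the default
  warm-up yields 4).
* **The faithful-copy window sits below its reference value.** At the
  nominal chain coupling of 8.2 nS (and throughout 8.18–8.27 nS) this
  implementation's chain *amplifies* the burst — the robustness sweep
  classifies all five reference couplings as "growing" — so faithful
  4-spike copying requires a somewhat weaker synapse than tabulated.
  Chain *timing* is unaffected: the burst-onset interval between chain
  neurons 2 and 25 is ~52 ms against a ~50 ms reference, and adjacent
  neurons fire ~2.3 ms apart.

Both deviations trace to the same property — the excitability of the
projection-neuron model as parameterized — and could not be reduced
further without altering tabulated values, which the package refuses to
do. Users exploring the copy regime should sweep `g_chain` with
`sweep_conductance()` rather than assume the tabulated window.
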