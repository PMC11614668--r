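# hvcnet

Biophysical simulator of the songbird premotor nucleus **HVC**, the timing
hub of the zebra finch song system. During each song motif every HVC
projection neuron (HVC\_RA) fires a single stereotyped burst of ~4 spikes
at a fixed moment, and the population's sequential bursts are thought to
clock the motif. `hvcnet` builds and integrates a conductance-based model
of that machinery for computational neuroscientists who want to probe it:
two Hodgkin–Huxley neuron classes, kinetic chemical synapses, a midbrain
(A11) neuromodulatory trigger pulse, and the feedforward excitatory chain
through which the burst pattern propagates.

## The model

**Neurons.** Membrane voltage obeys
`C dV/dt = I_Na + I_K + I_L (+ I_CaT + I_H) + Σ I_syn + I_background`
with every current written depolarizing-positive, `I = g·gates·(E − V)`.
The HVC\_RA cell carries fast sodium (`m³h`), delayed-rectifier potassium
(`n⁴`) and leak channels; the interneuron (HVC\_I) adds a T-type calcium
current `I_CaT = g_CaT a³b³ · GHK(V, [Ca])` with a Goldman–Hodgkin–Katz
flux factor and calcium bookkeeping
`d[Ca]/dt = φ I_CaT + ([Ca]₀ − [Ca])/τ_Ca`, plus a
hyperpolarization-activated current `I_H = g_H H² (E_H − V)`. All gates
relax first-order toward `η(V) = ½ + ½ tanh((V − V_½)/ΔV)` with time
constant `τ(V) = τ₀ + τ₁(1 − tanh²((V − V_½)/ΔV))`.

**Synapses.** Presynaptic release is a sigmoid of presynaptic voltage,
`[T] = T_max / (1 + exp(−(V_pre − V_p)/K_p))`; postsynaptic AMPA or
GABA\_A receptors open as `dr/dt = α[T](1 − r) − βr` and deliver
`I_syn = g_max · r · (E_rev − V_post)`.

**Trigger.** Motif onset is gated by a transmitter pulse from A11 axons:
baseline `T_min`, exponential rise to a 2.84 mM peak over
`t_trans = τ_r ln(T_peak/T_min) ≈ 9.54 ms`, then exponential decay. The
pulse inhibits the tonically firing interneuron; the resulting pause
releases the first projection neuron, whose burst is passed down a chain
of 50 HVC\_RA cells (`g = 10 nS` on the first edge, `8.2 nS` afterwards).

Networks are integrated with a fixed-step classical 4th-order Runge–Kutta
scheme at `dt = 0.02 ms` (step-halving convergence checks built in).

## Worked example

The two-cell microcircuit (A11 → interneuron, interneuron ⇄ projection
neuron) with the default trigger at 10 ms:

```r
library(hvcnet)

fx <- generate_fixture("fig5")       # bidirectional microcircuit
tr <- simulate_network(fx$network, fx$cfg)
tr
#> <hvc_traces> 2 neurons, 6001 samples, dt = 0.02 ms, 120 ms total

spikes <- spike_table(tr)
group_bursts(spikes$time[spikes$neuron == 2])
#>   onset offset duration n_spikes mean_isi
#> 1 21.24  26.16     4.92        4     1.64
```

The projection neuron, silenced by interneuron inhibition for the whole
pre-trigger period, fires exactly one 4-spike burst (onset 21.2 ms,
duration 4.9 ms) in the window the trigger opens: the pulse peaks at
`10 + 9.54 ms`, the interneuron falls silent (no interneuron spikes in
15–25 ms), and resumes once the projection neuron's own AMPA feedback
re-excites it. `generate_fixture()` provides the other reference
experiments (isolated cells, unidirectional circuit, 50-neuron chain,
conductance and baseline sweeps); `rheobase_search()`,
`chain_summary()`, `sweep_conductance()` and `check_convergence()` cover
the analyses. A thin command-line front end is included:

```sh
Rscript inst/exec/hvcnet fixture fig7 --out chain.json
Rscript inst/exec/hvcnet simulate chain.json --out chain
Rscript inst/exec/hvcnet rheobase --kind HVC_RA
```

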