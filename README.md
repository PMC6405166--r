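# ffinet

Simulation and analysis of canonical feedforward-inhibition microcircuits
with electrically coupled interneurons.

## The scientific problem

The disynaptic feedforward-inhibition motif — an excitatory source (Src)
driving both a target principal cell (Tgt) and an inhibitory interneuron
(Int) that in turn inhibits the same target — recurs throughout the brain
(dentate→CA1, thalamocortical projections to layer 4, translaminar cortical
circuits). The interneurons of such circuits are frequently connected to one
another by gap junctions (electrical synapses), whose strength is itself
plastic. `ffinet` is for computational neuroscientists who want to ask: what
does the strength of electrical coupling between the interneurons do to the
way transient inputs are integrated and relayed?

The package provides three model configurations built from Izhikevich
neurons:

* **SCC** — the simple canonical circuit: Src (regular spiking), Int (fast
  spiking), Tgt (regular spiking); 3 cells, 3 chemical synapses;
* **CCC** — two canonical arms converging on one shared target, with
  optional electrical and reciprocal GABAergic coupling between the two
  interneurons; 5 cells;
* **CCN** — a network of 50 feedforward subunits whose interneuron
  population is coupled all-to-all, each summed coupling conductance scaled
  by the population size (`G = ΣG / N_Int`).

## The model

Each neuron follows the two-variable quadratic integrate-and-fire dynamics

```
C dv/dt = k (v − v_r)(v − v_t) − u + I_app + I_syn
  du/dt = a · f(v, u),   with reset  v ≥ v_p → { v ← c,  u ← u + d }
```

where `f(v,u) = b(v − v_r) − u` for RS cells and `f(v,u) = U(v) − u` for FS
cells, `U(v) = 0` below `v_b` and `b (v − v_b)³` above it. Synapses are
conductance-based single-exponential gates, `I_chem = G s (E − v_post)`,
`ds/dt = −s/τ + Σ_k δ(t − t_k)` (AMPA: E = 0 mV, τ = 2 ms; GABA: E = −80 mV,
τ = 10 ms), and gap junctions are symmetric resistive couplings
`I_elec = G_elec (v_pre − v_post)`. Integration is fixed-step forward Euler
(dt = 0.01 ms for subthreshold work, 0.05 ms for the network).

Analyses include compound-PSP integration metrics (peak, integration window,
AUC), smoothed spike-time-density statistics normalised to the source
population, and the Src→Tgt mutual information / transmission efficiency
(`100·I(Src,Tgt)/H(Tgt)`) of first-spike times, with max + 2 SD imputation of
silent unit-trials.

## Worked example

```r
library(ffinet)

# gap-junction strength vs coupling coefficient
coupling_coefficient(8)$cc                  # 0.345  (simulated pair)
analytic_coupling_coefficient(8)$cc         # 0.348  (linearised prediction)

# the canonical compound PSP
net <- build_scc()                          # G_AMPA->Tgt 3 nS, G_GABA->Tgt 6 nS
sim <- run_network(net, pulse_schedule(net, t0 = 50), duration = 150,
                   record_v = TRUE)
tr  <- neuron_trace(sim, net, "Tgt")
psp_metrics(tr$v, tr$times, onset = 50)
#> PSP peak 1.881 mV, window 4.13 ms, AUC 4.23 mV*ms (baseline -60.00 mV)

# the uncoupled 50-unit network is a perfect timing channel
res <- run_ccn_condition(sigma_inp = 5, sum_g_elec = 0, sum_g_gaba_int = 0,
                         n_units = 50, n_trials = 50, seed = 1)
res$stats[, c("response_rate", "mi", "efficiency")]
#>   response_rate       mi efficiency
#> 1           100 8.507225        100
```

The PSP numbers say: a single source spike depolarises the target by ~1.9 mV,
but feedforward inhibition closes the window for summation after ~4 ms. The
network numbers say: with no interneuron coupling, every source spike is
relayed with a fixed latency, so all of the target's timing entropy is
attributable to the input (efficiency 100%).

The numbered scripts under `analysis/` run the full sweeps — SCC conductance
grids, CCC delay × coupling grids, and the CCN population and information
analyses — and write tidy CSV tables under `results/`.

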