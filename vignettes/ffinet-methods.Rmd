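---
title: "Models and methods behind ffinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ffinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffinet)
```

`ffinet` simulates canonical feedforward-inhibition circuits whose
interneurons are coupled by electrical synapses, and quantifies how coupling
strength shapes subthreshold integration in the target cell and the timing
statistics and information content of the target population's spikes. This
vignette is the package's own account of the models, the numerical choices,
and the points where the design was genuinely open.

## Neuron model

All cells are two-variable Izhikevich neurons,

$$C\,\dot v = k (v - v_r)(v - v_t) - u + I_\mathrm{app} + I_\mathrm{syn},
\qquad \dot u = a\, f(v, u),$$

with the discontinuous reset $v \ge v_p \Rightarrow v \leftarrow c,\ u
\leftarrow u + d$. Source and target cells are regular spiking (RS,
$f = b(v - v_r) - u$); interneurons are fast spiking (FS, $f = U(v) - u$
with $U(v) = 0$ for $v < v_b$ and $b (v - v_b)^3$ above). The presets live
in a plain JSON registry (`inst/extdata/izhikevich_params.json`, exposed via
`izhikevich_params()`):

| parameter | Src (RS) | Int (FS) | Tgt, subthreshold (RS) | Tgt, network (RS) |
|---|---|---|---|---|
| C (pF) | 100 | 20 | 100 | 50 |
| v_r (mV) | −60 | −55 | −60 | −60 |
| v_t (mV) | −40 | −40 | −40 | −45 |
| v_p (mV) | 35 | 25 | 35 | 35 |
| k (nS) | 0.7 | 1 | 0.7 | 0.7 |
| a (1/ms) | 0.03 | 0.2 | 0.03 | 0.03 |
| b (nS) | −2 | 0.025 | −2 | −2 |
| c (mV) | −50 | −45 | −50 | −50 |
| d (pA) | 100 | 0 | 100 | 100 |
| v_b (mV) | — | −55 | — | — |

The two target variants matter: in the single and coupled circuits the
target is studied subthreshold, while the network target has halved
capacitance, a 5 mV lower threshold and a 10 pA holding current so that a
single source spike reliably evokes a target spike 5–6 ms later.
Interneurons always carry a 50 pA holding current, which sits just below
their rheobase: the FS fixed point exists and is stable there
(`fs_fixed_point(50)` gives −50.4 mV), so the cell rests but a single EPSP
drives it to fire.

## Synapses

Chemical synapses are single-exponential conductances,
$I = G\,s\,(E - v_\mathrm{post})$, $\dot s = -s/\tau + \sum_k \delta(t -
t_k)$, with fixed kinetics (AMPA: $E = 0$ mV, $\tau = 2$ ms; GABA: $E = -80$
mV, $\tau = 10$ ms) and all weight carried by $G$; each presynaptic spike
increments the dimensionless gate by exactly 1, so coincident spikes sum.
Electrical synapses are symmetric resistive couplings, $I =
G_\mathrm{elec} (v_\mathrm{pre} - v_\mathrm{post})$, evaluated from the
instantaneous pre-reset membrane potentials every step — including during
the one step of the spike upstroke, which is precisely what transmits
spikelets to coupled neighbours. No synapse has an axonal delay: a spike in
step $k$ first drives its targets in step $k+1$.

In the network configuration the interneuron population is coupled
all-to-all, and each summed conductance (electrical, and reciprocal GABA
when enabled) is divided by the number of interneurons,
$G = \Sigma G / N_\mathrm{Int}$. Self-connections are excluded but the
divisor remains $N_\mathrm{Int}$; with the population at 50 the distinction
is a 2% effect, far below every tolerance used here. In the five-cell
coupled circuit the pairwise conductance is used raw (0–8 nS), since the
scaling rule is a population construct.

## Circuit configurations and conductances

| connection | SCC | CCC | CCN |
|---|---|---|---|
| Src→Int (AMPA, nS) | 10 | 10 | 5 |
| Src→Tgt (AMPA, nS) | 1–10 (default 3) | 3 | 20 |
| Int→Tgt (GABA, nS) | 1–10 (default 6) | 6–10 (default 8) | 10 |
| Int↔Int electrical (nS) | — | 0–8 | Σ 0–5 |
| Int↔Int GABA (nS) | — | 0–7 | Σ 0–5 |

Each feedforward arm is strictly within-subunit: Src$_i$ excites Int$_i$
and Tgt$_i$, and Int$_i$ inhibits only Tgt$_i$; only the interneuron
coupling spans subunits. This was a genuinely open design point, and we
checked the alternative: pooling the Int→Tgt inhibition across the
population (each target inhibited by every interneuron at $G/N$) destroys
the defining behaviour of the uncoupled network — with it, the uncoupled
response rate falls to ~85% and transmission efficiency to ~67%, whereas
the uncoupled network must relay every input with a fixed latency (100%
response, 100% efficiency, which the within-unit wiring reproduces
exactly). The within-unit reading is therefore the one consistent with the
model family's stated behaviour.

## Stimuli

Only source neurons receive external input: a DC boxcar of 250 pA for 25 ms
(midpoints of the plausible 200–300 pA, 20–30 ms ranges), calibrated so that
an isolated source fires exactly one spike — asserted in the test suite.
The boxcar is closed at onset and open at offset, so it occupies exactly
$d/\mathrm{dt}$ steps. Two regimes are provided:

* **paired inputs** (`paired_schedule`): two identical pulses with an exact
  inter-input delay $\Delta t_\mathrm{inp}$ of 0–20 ms, for the subthreshold
  circuits;
* **Gaussian jitter** (`gaussian_schedule`): one onset per source drawn from
  $\mathcal N(t_0, \sigma_\mathrm{inp}^2)$, $\sigma_\mathrm{inp}$ 1–10 ms,
  redrawn independently for every source neuron in every trial. Schedules
  reaching before $t = 0$ are rejected rather than truncated.

All randomness flows from one root seed: `run_trials()` derives per-trial
child seeds deterministically, and the schedule generators save and restore
the global RNG state so a sweep is reproducible end to end.

## Simulation engine

The inner loop (`src/engine.cpp`) is fixed-step forward Euler with a
documented within-step order: synaptic and applied currents from the
current states → Euler update of all $(v, u)$ using the pre-reset $v$ →
gate decay → reset detection (spike time recorded at the end of the step,
no threshold interpolation) → gate increments. Default steps are 0.01 ms
(100 ms subthreshold protocols) and 0.05 ms (200 ms network protocols); at
these steps halving dt leaves every spike count unchanged and moves spike
times by at most ~1.5 steps, which is the accuracy regime the analyses
need. A sanity guard aborts if any membrane potential leaves ±200 mV.

Before stimulation every network is settled for 1000 ms under holding
currents alone and the final state reused as the initial condition for all
trials. The long settle is deliberate: it parks each cell at its
double-precision fixed point, so that trial-to-trial differences come only
from the stimulus draw. This is what makes the uncoupled network an exactly
deterministic channel (every subunit's input-to-spike latency is constant
to the step), and hence its transmission efficiency exactly 100%.

The compiled loop is cross-checked in the tests against an R reference
stepper composed from the exported single-step primitives
(`membrane_rhs`, `recovery_rhs`, `apply_reset`, `decay_gate`), agreeing to
$10^{-10}$ on voltages and exactly on spike times.

## Subthreshold metrics

The compound PSP is quantified relative to the baseline read at stimulus
onset (the settled holding state — relevant for cells whose holding current
shifts rest). The positive portion is the set of samples more than
$\varepsilon = 0.01$ mV above baseline; the threshold exists only to
suppress numerical chatter in the window definition, which is otherwise
pictorial. The integration window is the total time above $\varepsilon$
(robust if transient hyperpolarisation splits the epoch; for all default
protocols the epoch is single and the definitions coincide), the AUC is the
rectangle-rule integral of $v -$ baseline over that time, and `peak`
$\ge 0$ with `auc` $\le$ `peak` × `window` by construction. Traces that
reach the spike cut are rejected with a pointer to the spiking pipeline.

## Coupling coefficient

`coupling_coefficient()` measures the classic pair experiment: two FS
interneurons coupled at $G$, a small sustained DC step into one, and the
steady-state deflection ratio $\Delta v_2 / \Delta v_1$. The default
measurement is at rest with a small hyperpolarising step, keeping the pair
in the linear regime below $v_b$ where the FS cubic is silent. The
independent closed-form check linearises about the fixed point with the
recovery variable fully adapted: $g_\mathrm{eff} = -k (2v - v_r - v_t) +
U'(v)$ and $cc = G/(g_\mathrm{eff} + G)$. At rest $g_\mathrm{eff} = 15$ nS,
so 8 nS of coupling gives $cc = 8/23 = 0.348$ — the conventional "coupling
of ~1/3" regime. Note that the coefficient is state-dependent: at the 50 pA
holding point the effective leak drops to 7.4 nS and the same 8 nS junction
measures $cc \approx 0.52$. Both operating points are verified against the
analytic prediction in the tests; the headline 0–0.33 range refers to the
resting measurement.

## Spike-time densities and normalised statistics

Population spike times (pooled over neurons and trials) are histogrammed at
a bin width of $\sigma_\mathrm{inp}/10$ — tying resolution to the input
spread avoids under-sampling tight distributions and over-sampling broad
ones — and smoothed with a 20-bin raised-cosine (Hanning) window. The
window is the MATLAB-style variant without zero endpoints; since the same
window is applied to the source and target densities, every ratio statistic
is invariant to its exact mass. The convolution keeps the central
("same") segment, and the histogram range is padded by ten window-widths so
edge effects are confined to empty tails. The smoothed densities are
deliberately **not** normalised by sample count: they are smoothed count
densities, and only ratios against the source density are interpreted.

Five statistics summarise a population against the source: normalised mean
(difference of means, ms), normalised SD (ratio), normalised maximum
density (ratio), normalised total response (ratio of areas, equal to the
spike-count ratio because the window mass is conserved), and relative
latency — the first time the density reaches 10% of its maximum, minus the
same measure for the source. The 10% threshold refers to each
distribution's *own* maximum by default (that is how normalised-density
insets with a 0.1 line are read); `latency_ref = "src"` switches to
10%-of-source-maximum for sensitivity analysis. Gains are plain differences
from the electrically uncoupled condition with all other parameters equal,
so the uncoupled column of any gain table is identically zero.

## Information metrics

The network is treated as a timing channel per subunit: one (Src$_i$,
Tgt$_i$) first-spike pair per trial, 2500 pairs at the reference sizes.
Marginals are plug-in histograms at a fixed 0.01 ms bin; the joint is the
unsmoothed 2-d histogram of the pairs at the same bin; mutual information
is $I = H(\mathrm{Src}) + H(\mathrm{Tgt}) - H(\mathrm{Src},\mathrm{Tgt})$
and transmission efficiency $100\,I/H(\mathrm{Tgt})$. No smoothing and no
bias correction are applied anywhere on this path: the estimator is the
plain plug-in, and comparisons across conditions are internally consistent
because the sample size is fixed by the protocol. Silent unit-trials are
imputed at $\max(X) + 2\,\mathrm{sd}(X)$ from the observed spikes of that
population and condition (computed once, before any imputation), which
keeps both marginals and the joint defined without discarding trials; a
fixed sentinel (e.g. 1000 ms) is available for demonstrations. Multi-spike
responses use the first spike; at the default conductances every population
fires at most once per stimulus.

Two facts worth keeping in mind when reading efficiency tables: the
plug-in MI of *independent* channels is biased upward at these sample
sizes (the tests quantify it on shuffled pairs), and efficiencies are only
compared within a fixed protocol size for exactly that reason.

## Problem sizes and reproducibility

The reference protocol is 50 subunits × 50 trials per condition, simulated
for 200 ms at dt = 0.05 ms; subthreshold circuits run 100–150 ms at
dt = 0.01 ms. The full test suite exercises the complete protocol (including
a 20-condition × 50-trial efficiency sweep) in under a minute of CPU time,
and `scripts/acceptance.R` reruns the two headline network quantities from
scratch in about half a minute. The `analysis/` scripts run the larger
figure-style grids (80 network conditions; ~1500 subthreshold circuits) in
a few minutes.

## Known limitations

* The synthetic stimuli are clean DC steps with timed onsets; there is no
  background synaptic bombardment, no noise term, and no heterogeneity
  across subunits. Passing tests therefore demonstrate properties of the
  idealised circuit family, not robustness to biological variability.
* Gap junctions are ohmic and static; rectifying or activity-dependent
  electrical synapses are out of scope.
* Forward Euler with no threshold interpolation quantises spike times to
  the step; all statistics inherit that 0.01–0.05 ms granularity, which is
  well below every bin width used.
* The plug-in information estimates are protocol-size-dependent; they are
  meant for within-protocol comparisons, not as absolute channel
  capacities.
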