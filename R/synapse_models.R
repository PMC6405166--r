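#' Reversal potential and decay constant for a chemical synapse class
#'
#' AMPA: E = 0 mV, tau = 2 ms. GABA: E = -80 mV, tau = 10 ms. These are fixed
#' constants of the model family; conductances vary per connection.
#'
#' @param kind `"AMPA"` or `"GABA"`.
#' @return List with `E` (mV) and `tau` (ms).
#' @export
synapse_kinetics <- function(kind = c("AMPA", "GABA")) {
  kind <- match.arg(kind)
  switch(kind,
         AMPA = list(E = 0,   tau = 2),
         GABA = list(E = -80, tau = 10))
}

#' Gap-junction current
#'
#' `I_elec = G_elec (v_pre - v_post)` in pA (nS x mV). The coupling is
#' symmetric: the partner cell receives the same current with opposite sign,
#' so the summed current over a coupled pair is identically zero.
#'
#' @param g_elec Coupling conductance (nS), non-negative.
#' @param v_pre,v_post Membrane potentials (mV) of the two coupled cells.
#' @return Current into the `post` cell (pA).
#' @export
electrical_current <- function(g_elec, v_pre, v_post) {
  stopifnot(all(g_elec >= 0))
  g_elec * (v_pre - v_post)
}

#' Conductance-based chemical synaptic current
#'
#' `I_chem = G s (E - v_post)` in pA, with dimensionless gate `s`.
#'
#' @param g Maximal conductance (nS).
#' @param s Gate state (dimensionless, >= 0).
#' @param e_rev Reversal potential (mV).
#' @param v_post Postsynaptic membrane potential (mV).
#' @return Current into the postsynaptic cell (pA).
#' @export
chemical_current <- function(g, s, e_rev, v_post) {
  stopifnot(all(s >= 0))
  g * s * (e_rev - v_post)
}

#' One Euler step of gate decay
#'
#' The gate obeys `ds/dt = -s / tau` between presynaptic spikes, so a single
#' fixed step multiplies `s` by `(1 - dt/tau)`; over elapsed time `t` the
#' closed-form factor is `exp(-t/tau)`.
#'
#' @param s Gate state.
#' @param tau Decay constant (ms).
#' @param dt Step size (ms), positive and smaller than `tau`.
#' @return Decayed gate state.
#' @export
decay_gate <- function(s, tau, dt) {
  stopifnot(dt > 0, tau > 0)
  s - dt * s / tau
}

#' Gate increment on presynaptic spikes
#'
#' Each presynaptic spike adds a unit delta to the gate; closely timed spikes
#' sum. Conductance scaling is carried entirely by `G`.
#'
#' @param s Gate state.
#' @param n_spikes Number of presynaptic spikes registered this step.
#' @return Updated gate state.
#' @export
on_presynaptic_spike <- function(s, n_spikes = 1) {
  s + n_spikes
}

#' Per-connection conductance for all-to-all interneuron coupling
#'
#' In the network configuration the interneuron population is coupled
#' all-to-all and each summed conductance (electrical or reciprocal GABA) is
#' divided by the number of interneurons: `G = sum(G) / N_Int`. Self
#' connections are excluded from the wiring but the divisor remains `N_Int`.
#'
#' @param total Summed population conductance (nS), non-negative.
#' @param n_int Number of interneurons (>= 1).
#' @return Per-connection conductance (nS).
#' @export
scale_population_coupling <- function(total, n_int) {
  if (any(n_int < 1)) stop("n_int must be >= 1")
  stopifnot(all(total >= 0))
  total / n_int
}
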