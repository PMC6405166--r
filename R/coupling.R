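## Gap-junction coupling strength, measured and predicted. The coupling
## coefficient (cc) is the steady-state voltage deflection in the coupled
## neighbour divided by the deflection in the injected cell.

#' Measure the coupling coefficient of an electrically coupled FS pair
#'
#' Builds two identical FS interneurons coupled at `g_elec`, settles them at
#' the holding current, injects a small sustained DC step into cell 1, and
#' reads the steady-state deflections of both cells. The default step is a
#' small hyperpolarisation so the pair stays in the linear subthreshold
#' regime. With the FS parameters at rest (no holding current) the effective
#' leak near `v_r` is 15 nS, so 8 nS of coupling gives cc close to 1/3.
#'
#' @param g_elec Electrical conductance (nS).
#' @param i_hold Holding current applied to both cells (pA).
#' @param i_step Injected DC step (pA); small and, by default, negative.
#' @param t_step Step duration (ms); long enough to reach steady state.
#' @param dt Integration step (ms).
#' @return List: `cc`, deflections `dv1`, `dv2` (mV), baseline `v0` (mV).
#' @export
coupling_coefficient <- function(g_elec = 8, i_hold = 0, i_step = -10,
                                 t_step = 400, dt = 0.01) {
  neurons <- rbind(neuron_row(1L, "Int", 1L, "Int", i_hold),
                   neuron_row(2L, "Int", 2L, "Int", i_hold))
  elec <- data.frame(pre = 1L, post = 2L, G = g_elec)
  net <- new_ff_network("PAIR", neurons, empty_chem(), elec)
  init <- settle_network(net, t_settle = 1000, dt = dt)
  sch <- new_schedule(data.frame(neuron = 1L, onset = 0, duration = t_step,
                                 amplitude = i_step), mode = "explicit")
  sim <- run_network(net, sch, duration = t_step, dt = dt,
                     record_v = TRUE, init = init)
  if (nrow(sim$spikes) > 0) stop("pair spiked; use a smaller i_step")
  n <- nrow(sim$v)
  v_end <- sim$v[n, ]
  dv <- v_end - init$v
  list(cc = dv[2] / dv[1], dv1 = dv[1], dv2 = dv[2], v0 = init$v[1])
}

#' Subthreshold fixed point of an FS interneuron under holding current
#'
#' Solves `k (v - v_r)(v - v_t) - U(v) + I_hold = 0` with the recovery
#' current at its steady value `u = U(v)`.
#'
#' @param i_hold Holding current (pA).
#' @return List: `v` (mV), `u` (pA).
#' @export
fs_fixed_point <- function(i_hold = 0) {
  p <- izhikevich_params("Int")
  U <- function(v) ifelse(v < p$v_b, 0, p$b * (v - p$v_b)^3)
  f <- function(v) p$k * (v - p$v_r) * (v - p$v_t) - U(v) + i_hold
  v <- stats::uniroot(f, lower = p$v_r - 40, upper = p$v_t - 5,
                      tol = 1e-12)$root
  list(v = v, u = U(v))
}

#' Analytic coupling coefficient from the linearised pair
#'
#' Linearising both cells about the holding fixed point (with the recovery
#' variable fully adapted, `u = U(v)`) gives an effective leak conductance
#' `g_eff = -k (2v - v_r - v_t) + U'(v)`; the steady-state deflection ratio
#' of the coupled pair is then `cc = G / (g_eff + G)`. Serves as the
#' independent closed-form check on [coupling_coefficient()].
#'
#' @inheritParams coupling_coefficient
#' @return List: `cc`, `g_eff` (nS), fixed-point `v` (mV).
#' @export
analytic_coupling_coefficient <- function(g_elec = 8, i_hold = 0) {
  p <- izhikevich_params("Int")
  fp <- fs_fixed_point(i_hold)
  dU <- if (fp$v < p$v_b) 0 else 3 * p$b * (fp$v - p$v_b)^2
  g_eff <- -p$k * (2 * fp$v - p$v_r - p$v_t) + dU
  list(cc = g_elec / (g_eff + g_elec), g_eff = g_eff, v = fp$v)
}
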