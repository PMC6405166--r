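## Synthetic stimulus generators. Only Src neurons receive external input:
## a brief DC pulse per source, with either a fixed inter-input delay
## (subthreshold experiments) or onsets jittered by a Gaussian of SD
## sigma_inp (network experiments).

#' Boxcar DC pulse
#'
#' `I(t) = I0` for `t` in `[t_inp, t_inp + d_inp)`, else 0. The interval is
#' closed at onset and open at offset so the pulse occupies exactly
#' `d_inp / dt` simulation steps.
#'
#' @param I0 Amplitude (pA); the reference stimulus range is 200-300 pA.
#' @param t_inp Onset (ms).
#' @param d_inp Duration (ms), positive; reference range 20-30 ms.
#' @param t Time(s) at which to evaluate (ms).
#' @return Current (pA), vectorised over `t`.
#' @export
dc_pulse <- function(I0, t_inp, d_inp, t) {
  stopifnot(d_inp > 0)
  ifelse(t >= t_inp & t < t_inp + d_inp, I0, 0)
}

new_schedule <- function(pulses, mode, meta = list()) {
  structure(pulses, mode = mode, meta = meta, class = c("ff_schedule", "data.frame"))
}

#' Pulse schedule with explicit onsets
#'
#' Assigns one DC pulse to each Src neuron of `net`, in Src id order.
#'
#' @param net An `ff_network`.
#' @param onsets Onset times (ms), one per Src neuron (or one, recycled).
#' @param I0 Pulse amplitude (pA). The default (250 pA for 25 ms) evokes
#'   exactly one spike in an isolated Src neuron.
#' @param d_inp Pulse duration (ms).
#' @return An `ff_schedule`: a data.frame with columns `neuron`, `onset`,
#'   `duration`, `amplitude`.
#' @export
pulse_schedule <- function(net, onsets, I0 = 250, d_inp = 25) {
  src <- neuron_ids(net, "Src")
  onsets <- rep_len(onsets, length(src))
  if (any(onsets < 0)) stop("pulse onsets must be >= 0")
  new_schedule(data.frame(neuron = src, onset = onsets,
                          duration = d_inp, amplitude = I0),
               mode = "explicit")
}

#' Paired-input schedule for the coupled circuit
#'
#' Two identical pulses with the input to Src_2 delayed by `delta_t` relative
#' to Src_1. Negative `delta_t` mirrors which source leads.
#'
#' @param net A CCC (or any two-source) network.
#' @param delta_t Inter-input delay (ms); the reference sweeps use 0-20 ms.
#' @param t0 Onset of the Src_1 pulse (ms), default 50 (after the settling
#'   buffer).
#' @inheritParams pulse_schedule
#' @return An `ff_schedule`.
#' @export
paired_schedule <- function(net, delta_t, t0 = 50, I0 = 250, d_inp = 25) {
  src <- neuron_ids(net, "Src")
  if (length(src) != 2) stop("paired_schedule needs a network with exactly 2 Src neurons")
  sch <- pulse_schedule(net, c(t0, t0 + delta_t), I0 = I0, d_inp = d_inp)
  attr(sch, "mode") <- "paired"
  attr(sch, "meta") <- list(delta_t = delta_t, t0 = t0)
  sch
}

#' Gaussian-jittered input schedule for the network
#'
#' Draws one onset per Src neuron from `Normal(t0, sigma_inp^2)`,
#' reproducibly under `seed`. Schedules whose earliest onset would precede
#' t = 0 are rejected; choose `t0` large enough.
#'
#' @param net A CCN (or any) network.
#' @param sigma_inp Input-timing SD (ms); the reference sweeps use 1-10 ms.
#' @param t0 Mean onset (ms), default 100.
#' @param seed Integer seed for the draw.
#' @inheritParams pulse_schedule
#' @return An `ff_schedule`.
#' @export
gaussian_schedule <- function(net, sigma_inp, t0 = 100, seed = 1,
                              I0 = 250, d_inp = 25) {
  stopifnot(sigma_inp > 0)
  src <- neuron_ids(net, "Src")
  onsets <- local({
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    stats::rnorm(length(src), mean = t0, sd = sigma_inp)
  })
  if (any(onsets < 0))
    stop("earliest onset precedes t = 0; increase t0 relative to sigma_inp")
  sch <- pulse_schedule(net, onsets, I0 = I0, d_inp = d_inp)
  attr(sch, "mode") <- "gaussian"
  attr(sch, "meta") <- list(sigma_inp = sigma_inp, t0 = t0, seed = seed)
  sch
}

# save/restore the global RNG state so schedule draws are self-contained
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
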