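## Quantification of the compound PSP in the target neuron: the summed
## excitatory-then-inhibitory deflection produced by one source spike through
## the direct AMPA path and the delayed disynaptic GABA path.

#' Compound PSP metrics for a subthreshold target trace
#'
#' The baseline is the membrane potential at stimulus onset (the settled
#' holding state). The positive portion of the PSP is the set of samples with
#' `v - baseline > eps`; `eps` (default 0.01 mV) suppresses numerical chatter
#' in the window definition. Reported are the peak depolarisation above
#' baseline (mV), the integration window (total time above `eps`, ms), and
#' the area under the positive portion (mV*ms, trapezoid-free rectangle sum
#' at the recording step).
#'
#' @param v Voltage samples of the target neuron (mV).
#' @param times Sample times (ms), same length as `v`.
#' @param onset Stimulus onset (ms): start of the analysis window and the
#'   time at which the baseline is read.
#' @param eps Positivity threshold above baseline (mV).
#' @param v_p Spike cut-off (mV); if the trace reaches it the target spiked
#'   and these subthreshold metrics are undefined.
#' @return List of class `psp_metrics`: `peak`, `window`, `auc`, `baseline`.
#' @export
psp_metrics <- function(v, times, onset, eps = 0.01, v_p = 35) {
  stopifnot(length(v) == length(times))
  i0 <- which(times >= onset)[1]
  if (is.na(i0)) stop("onset is beyond the end of the trace")
  seg <- v[i0:length(v)]
  if (any(seg >= v_p))
    stop("target spiked in the analysis window; use the spiking pipeline")
  baseline <- seg[1]
  dv <- seg - baseline
  dt <- diff(times[1:2])
  pos <- dv > eps
  peak <- max(0, max(dv))
  structure(list(peak = peak,
                 window = sum(pos) * dt,
                 auc = sum(dv[pos]) * dt,
                 baseline = baseline),
            class = "psp_metrics")
}

#' @export
print.psp_metrics <- function(x, ...) {
  cat(sprintf("PSP peak %.3f mV, window %.2f ms, AUC %.2f mV*ms (baseline %.2f mV)\n",
              x$peak, x$window, x$auc, x$baseline))
  invisible(x)
}

#' Voltage trace of one neuron from a recorded simulation
#'
#' @param sim An `ff_sim` with `record_v = TRUE`.
#' @param net The network the simulation ran on.
#' @param population,unit Which neuron to extract (first match).
#' @return List with `v` and `times`.
#' @export
neuron_trace <- function(sim, net, population = "Tgt", unit = 1) {
  if (is.null(sim$v)) stop("simulation was run without voltage recording")
  id <- neuron_ids(net, population, unit)[1]
  list(v = sim$v[, id], times = sim$times)
}

#' First-spike latency of one neuron relative to another
#'
#' @param spikes Spike data.frame (`neuron`, `time`) from a single run.
#' @param reference,target Neuron ids.
#' @return Latency (ms) of the target's first spike after the reference's
#'   first spike, or `NA` if either never spiked.
#' @export
relative_spike_latency <- function(spikes, reference, target) {
  t_ref <- spikes$time[spikes$neuron == reference]
  t_tgt <- spikes$time[spikes$neuron == target]
  if (length(t_ref) == 0 || length(t_tgt) == 0) return(NA_real_)
  min(t_tgt) - min(t_ref)
}
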