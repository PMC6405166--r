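## Clock-driven simulation front end. The inner loop lives in src/engine.cpp;
## these wrappers assemble the flat parameter vectors, manage the settling of
## holding-current steady states, and return tidy spike rasters.

default_dt <- function(net) if (net$config == "CCN") 0.05 else 0.01
default_duration <- function(net) if (net$config == "CCN") 200 else 100

engine_call <- function(net, pulses, duration, dt, v_init, u_init, record_v) {
  nn <- net$neurons
  sim_engine_cpp(nn$C, nn$v_r, nn$v_t, nn$v_p, nn$k, nn$a, nn$b, nn$c, nn$d,
                 ifelse(is.na(nn$v_b), 0, nn$v_b), nn$cell_type == "FS",
                 nn$I_hold,
                 as.integer(net$chem$pre) - 1L, as.integer(net$chem$post) - 1L,
                 net$chem$G, net$chem$E, net$chem$tau,
                 as.integer(net$elec$pre) - 1L, as.integer(net$elec$post) - 1L,
                 net$elec$G,
                 as.integer(pulses$neuron) - 1L, pulses$amplitude,
                 pulses$onset, pulses$duration,
                 dt, duration, v_init, u_init, record_v)
}

no_pulses <- function() {
  data.frame(neuron = integer(0), onset = numeric(0),
             duration = numeric(0), amplitude = numeric(0))
}

#' Settle a network to its holding steady state
#'
#' Runs the network with holding currents only (no stimulus) and returns the
#' final state. Used as the initial condition for stimulated runs so that the
#' pre-stimulus baseline is stationary; 1000 ms is far beyond every
#' relaxation time constant in the model (the slowest is ~33 ms).
#'
#' @param net An `ff_network`.
#' @param t_settle Settling time (ms).
#' @param dt Step size (ms); defaults to the configuration's step.
#' @return List with numeric vectors `v` and `u` (one entry per neuron).
#' @export
settle_network <- function(net, t_settle = 1000, dt = default_dt(net)) {
  nn <- net$neurons
  res <- engine_call(net, no_pulses(), t_settle, dt,
                     v_init = nn$v_r, u_init = rep(0, nrow(nn)),
                     record_v = FALSE)
  if (length(res$spike_time) > 0)
    warning("network spiked during settling; holding state is not a rest state")
  list(v = res$v_final, u = res$u_final)
}

#' Run one simulation
#'
#' Advances the whole network with fixed-step forward Euler. Within each step
#' the order is: synaptic and applied currents from the current states, Euler
#' update of all `(v, u)`, gate decay, spike resets, then gate increments for
#' synapses whose presynaptic neuron spiked this step (zero axonal delay:
#' a spike becomes effective on the following step).
#'
#' @param net An `ff_network`.
#' @param schedule An `ff_schedule` of DC pulses (or `NULL` for none).
#' @param duration Simulation length (ms). Defaults: 100 ms for SCC/CCC,
#'   200 ms for CCN.
#' @param dt Step (ms). Defaults: 0.01 ms for SCC/CCC, 0.05 ms for CCN.
#' @param record_v Record the full voltage trace of every neuron (needed for
#'   PSP metrics; off by default for network runs).
#' @param init Initial state as returned by [settle_network()]; computed on
#'   the fly if `NULL`.
#' @return An `ff_sim` list: `spikes` (data.frame `neuron`, `population`,
#'   `unit`, `time`), `v` (matrix steps+1 x neurons, if recorded), `times`,
#'   `duration`, `dt`, `final` state.
#' @export
run_network <- function(net, schedule = NULL,
                        duration = default_duration(net),
                        dt = default_dt(net),
                        record_v = net$config != "CCN",
                        init = NULL) {
  if (is.null(init)) init <- settle_network(net, dt = dt)
  pulses <- if (is.null(schedule)) no_pulses() else as.data.frame(schedule)
  res <- engine_call(net, pulses, duration, dt, init$v, init$u, record_v)
  idx <- res$spike_neuron
  spikes <- data.frame(neuron = idx,
                       population = net$neurons$population[idx],
                       unit = net$neurons$unit[idx],
                       time = res$spike_time)
  out <- list(spikes = spikes,
              v = if (record_v) res$v else NULL,
              times = if (record_v) seq(0, duration, by = dt) else NULL,
              duration = duration, dt = dt,
              final = list(v = res$v_final, u = res$u_final))
  class(out) <- "ff_sim"
  out
}

#' @export
print.ff_sim <- function(x, ...) {
  cat(sprintf("<ff_sim: %g ms at dt = %g ms, %d spikes>\n",
              x$duration, x$dt, nrow(x$spikes)))
  invisible(x)
}

#' Run repeated trials with per-trial stimulus draws
#'
#' Builds one schedule per trial via `schedule_fn(trial_seed)` and aggregates
#' the spikes into a single raster. Per-trial seeds are drawn once from the
#' root `seed`, so a rerun with the same root seed reproduces the raster
#' exactly; the network is settled once and the same initial state reused.
#'
#' @param net An `ff_network`.
#' @param schedule_fn Function taking a single integer seed and returning an
#'   `ff_schedule` (e.g. `function(s) gaussian_schedule(net, 5, seed = s)`).
#' @param n_trials Number of trials (the reference protocol uses 50).
#' @param seed Root integer seed.
#' @inheritParams run_network
#' @return A raster data.frame (`trial`, `neuron`, `population`, `unit`,
#'   `time`) with attributes `n_trials`, `n_units`, `trial_seeds`.
#' @export
run_trials <- function(net, schedule_fn, n_trials, seed = 1,
                       duration = default_duration(net),
                       dt = default_dt(net)) {
  stopifnot(n_trials >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max %/% 2, n_trials)
  init <- settle_network(net, dt = dt)
  rasters <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sim <- run_network(net, schedule_fn(trial_seeds[k]),
                       duration = duration, dt = dt,
                       record_v = FALSE, init = init)
    if (nrow(sim$spikes) > 0) {
      sim$spikes$trial <- k
      rasters[[k]] <- sim$spikes
    }
  }
  raster <- do.call(rbind, rasters)
  if (is.null(raster))
    raster <- data.frame(neuron = integer(0), population = character(0),
                         unit = integer(0), time = numeric(0), trial = integer(0))
  raster <- raster[, c("trial", "neuron", "population", "unit", "time")]
  rownames(raster) <- NULL
  attr(raster, "n_trials") <- n_trials
  attr(raster, "n_units") <- net$n_units
  attr(raster, "trial_seeds") <- trial_seeds
  raster
}

#' First spike time per unit and trial
#'
#' Extracts, for one population, the first spike time of each subunit in each
#' trial as a units x trials matrix; `NA` marks a unit-trial with no spike.
#'
#' @param raster A raster from [run_trials()].
#' @param population `"Src"`, `"Int"` or `"Tgt"`.
#' @param n_units,n_trials Dimensions; taken from the raster attributes when
#'   omitted.
#' @return Numeric matrix `n_units` x `n_trials` of times (ms).
#' @export
first_spike_times <- function(raster, population,
                              n_units = attr(raster, "n_units"),
                              n_trials = attr(raster, "n_trials")) {
  sub <- raster[raster$population == population, ]
  m <- matrix(NA_real_, n_units, n_trials)
  if (nrow(sub) > 0) {
    ord <- order(sub$time)
    sub <- sub[ord, ]
    first <- !duplicated(sub[, c("unit", "trial")])
    sub <- sub[first, ]
    m[cbind(sub$unit, sub$trial)] <- sub$time
  }
  m
}
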