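## Sweep drivers behind the analysis scripts, the tests and the acceptance
## script. Each returns a tidy data.frame with one row per grid point.

#' Subthreshold PSP sweep of the simple canonical circuit
#'
#' For every combination of Src->Tgt AMPA and Int->Tgt GABA conductance,
#' builds an SCC, delivers the default pulse to Src and quantifies the
#' compound PSP in Tgt.
#'
#' @param g_ampa_tgt Vector of Src -> Tgt conductances (nS).
#' @param g_gaba_tgt Vector of Int -> Tgt conductances (nS).
#' @param t0 Stimulus onset (ms).
#' @param duration Simulation length (ms); long enough for the PSP to decay.
#' @return Tidy data.frame: `g_ampa_tgt`, `g_gaba_tgt`, `peak`, `window`,
#'   `auc`.
#' @export
sweep_scc <- function(g_ampa_tgt = 1:10, g_gaba_tgt = 1:10,
                      t0 = 50, duration = 150) {
  grid <- expand.grid(g_ampa_tgt = g_ampa_tgt, g_gaba_tgt = g_gaba_tgt)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    net <- build_scc(g_ampa_tgt = grid$g_ampa_tgt[i],
                     g_gaba_tgt = grid$g_gaba_tgt[i])
    sim <- run_network(net, pulse_schedule(net, t0),
                       duration = duration, record_v = TRUE)
    tr <- neuron_trace(sim, net, "Tgt")
    m <- psp_metrics(tr$v, tr$times, t0)
    cbind(grid[i, , drop = FALSE],
          peak = m$peak, window = m$window, auc = m$auc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subthreshold sweep of the coupled canonical circuit
#'
#' For every combination of inter-input delay, interneuron electrical
#' coupling and reciprocal interneuron inhibition, runs the CCC and reports
#' the Tgt PSP metrics and the two interneurons' spike latencies relative to
#' Src_1.
#'
#' @param delta_t Vector of inter-input delays (ms).
#' @param g_elec Vector of Int-Int electrical conductances (nS).
#' @param g_gaba_int Vector of reciprocal Int-Int GABA conductances (nS).
#' @param g_gaba_tgt Int -> Tgt conductance (nS).
#' @inheritParams sweep_scc
#' @return Tidy data.frame with the grid, `peak`, `window`, `auc`,
#'   `lat_int1`, `lat_int2`.
#' @export
sweep_ccc <- function(delta_t = seq(0, 20, by = 2), g_elec = 0,
                      g_gaba_int = 0, g_gaba_tgt = 8,
                      t0 = 50, duration = 150) {
  grid <- expand.grid(delta_t = delta_t, g_elec = g_elec,
                      g_gaba_int = g_gaba_int)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    net <- build_ccc(g_elec = grid$g_elec[i], g_gaba_int = grid$g_gaba_int[i],
                     g_gaba_tgt = g_gaba_tgt)
    sim <- run_network(net, paired_schedule(net, grid$delta_t[i], t0 = t0),
                       duration = duration, record_v = TRUE)
    tr <- neuron_trace(sim, net, "Tgt")
    m <- psp_metrics(tr$v, tr$times, t0)
    cbind(grid[i, , drop = FALSE],
          peak = m$peak, window = m$window, auc = m$auc,
          lat_int1 = relative_spike_latency(sim$spikes, 1L, 3L),
          lat_int2 = relative_spike_latency(sim$spikes, 1L, 4L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One network (CCN) condition: raster plus all population statistics
#'
#' Runs `n_trials` trials of the CCN with Gaussian-jittered input times and
#' returns the raster together with the normalised distribution statistics
#' for the Int and Tgt populations and the Src->Tgt information metrics.
#'
#' @param sigma_inp Input-timing SD (ms).
#' @param sum_g_elec Summed interneuron electrical conductance (nS).
#' @param sum_g_gaba_int Summed reciprocal interneuron inhibition (nS).
#' @param n_units Number of subunits.
#' @param n_trials Number of trials.
#' @param seed Root seed.
#' @param t0 Mean input onset (ms).
#' @param keep_raster Return the raster as well (memory).
#' @return List: `stats` (one-row data.frame with the grid point, Tgt and Int
#'   distribution statistics, response rate, entropies, MI and efficiency)
#'   and optionally `raster`.
#' @export
run_ccn_condition <- function(sigma_inp, sum_g_elec = 0, sum_g_gaba_int = 0,
                              n_units = 50, n_trials = 50, seed = 1,
                              t0 = 100, keep_raster = FALSE) {
  net <- build_ccn(n_units, sum_g_elec, sum_g_gaba_int)
  raster <- run_trials(net,
                       function(s) gaussian_schedule(net, sigma_inp, t0 = t0, seed = s),
                       n_trials = n_trials, seed = seed)
  src_times <- raster$time[raster$population == "Src"]
  tgt_times <- raster$time[raster$population == "Tgt"]
  int_times <- raster$time[raster$population == "Int"]
  tgt_stats <- distribution_stats(tgt_times, src_times, sigma_inp)
  int_stats <- distribution_stats(int_times, src_times, sigma_inp)
  names(int_stats) <- paste0("int_", names(int_stats))
  info <- transmission_efficiency(raster)
  stats <- cbind(
    data.frame(sigma_inp = sigma_inp, sum_g_elec = sum_g_elec,
               sum_g_gaba_int = sum_g_gaba_int,
               n_units = n_units, n_trials = n_trials, seed = seed),
    tgt_stats, int_stats,
    data.frame(response_rate = info$response_rate,
               H_src = info$H_src, H_tgt = info$H_tgt,
               H_joint = info$H_joint, mi = info$mi,
               efficiency = info$efficiency))
  out <- list(stats = stats)
  if (keep_raster) out$raster <- raster
  out
}

#' Grid sweep of the CCN
#'
#' Runs [run_ccn_condition()] over the cross product of input spreads,
#' electrical coupling strengths and reciprocal inhibition levels. Per-cell
#' seeds are derived deterministically from the root seed, so the sweep is
#' reproducible and any sub-grid rerun under the same root seed matches.
#'
#' @param sigma_grid Input-timing SDs (ms); reference grid `c(1, 3, 5, 10)`.
#' @param g_elec_grid Summed electrical conductances (nS); reference grid
#'   `c(0, 1, 2, 3, 4.5)`.
#' @param g_gaba_int_grid Summed reciprocal inhibition (nS); reference grid
#'   `c(0, 1, 3, 5)`.
#' @inheritParams run_ccn_condition
#' @return Tidy data.frame, one row per grid point (the `stats` rows).
#' @export
sweep_ccn <- function(sigma_grid = c(1, 3, 5, 10),
                      g_elec_grid = c(0, 1, 2, 3, 4.5),
                      g_gaba_int_grid = 0,
                      n_units = 50, n_trials = 50, seed = 1, t0 = 100) {
  grid <- expand.grid(sigma_inp = sigma_grid, sum_g_elec = g_elec_grid,
                      sum_g_gaba_int = g_gaba_int_grid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # seed each cell by its position so sub-grids reproduce under the same root
  cell_seeds <- sample.int(.Machine$integer.max %/% 2, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    run_ccn_condition(grid$sigma_inp[i], grid$sum_g_elec[i],
                      grid$sum_g_gaba_int[i],
                      n_units = n_units, n_trials = n_trials,
                      seed = cell_seeds[i], t0 = t0)$stats
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Add gains relative to the electrically uncoupled column
#'
#' For each statistic named in `cols`, appends `gain_<col>`: the difference
#' from the same statistic at `sum_g_elec = 0` with matching `sigma_inp` and
#' `sum_g_gaba_int`. The uncoupled column is identically zero by definition.
#'
#' @param sweep A data.frame from [sweep_ccn()].
#' @param cols Statistic columns to express as gains.
#' @return `sweep` with the gain columns appended.
#' @export
add_gains <- function(sweep, cols = c("norm_mean", "norm_sd",
                                      "norm_max_density", "norm_total",
                                      "rel_latency", "efficiency")) {
  base <- sweep[sweep$sum_g_elec == 0, ]
  if (nrow(base) == 0) stop("sweep has no sum_g_elec = 0 column")
  key <- function(df) paste(df$sigma_inp, df$sum_g_gaba_int)
  idx <- match(key(sweep), key(base))
  for (cl in cols) sweep[[paste0("gain_", cl)]] <- gain(sweep[[cl]], base[[cl]][idx])
  sweep
}

#' Largest efficiency drop relative to the uncoupled network
#'
#' Maximum over the sweep grid of (efficiency at `sum_g_elec = 0`) minus
#' (efficiency at `sum_g_elec > 0`), in percentage points.
#'
#' @param sweep A data.frame from [sweep_ccn()] including the uncoupled
#'   column.
#' @return List: `drop` (percentage points), `at` (the grid row attaining
#'   it).
#' @export
max_efficiency_drop <- function(sweep) {
  sw <- add_gains(sweep, cols = "efficiency")
  coupled <- sw[sw$sum_g_elec > 0, ]
  i <- which.min(coupled$gain_efficiency)
  list(drop = -coupled$gain_efficiency[i],
       at = coupled[i, c("sigma_inp", "sum_g_elec", "sum_g_gaba_int",
                         "efficiency")])
}
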