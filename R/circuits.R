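## Circuit builders: the three canonical configurations.
##
## SCC: one Src (RS) -> one Int (FS) and one Tgt (RS); Int -> Tgt GABA.
## CCC: two such feedforward arms sharing a common Tgt, with optional
##      electrical and reciprocal GABA coupling between the two Ints.
## CCN: n subunits (Src_i -> Int_i -> Tgt_i, Src_i -> Tgt_i) with the whole
##      Int population coupled all-to-all (electrical, and optionally GABA),
##      each summed conductance scaled by N_Int.

new_ff_network <- function(config, neurons, chem, elec) {
  structure(list(config = config,
                 n_units = max(neurons$unit),
                 neurons = neurons,
                 chem = chem,
                 elec = elec),
            class = "ff_network")
}

neuron_row <- function(id, population, unit, preset, i_hold) {
  p <- izhikevich_params(preset)
  data.frame(id = id, population = population, unit = unit, preset = preset,
             cell_type = p$cell_type, C = p$C, v_r = p$v_r, v_t = p$v_t,
             v_p = p$v_p, k = p$k, a = p$a, b = p$b, c = p$c, d = p$d,
             v_b = p$v_b, I_hold = i_hold, stringsAsFactors = FALSE)
}

chem_row <- function(pre, post, kind, g) {
  kin <- synapse_kinetics(kind)
  data.frame(pre = pre, post = post, kind = kind, G = g,
             E = kin$E, tau = kin$tau, stringsAsFactors = FALSE)
}

empty_chem <- function() {
  data.frame(pre = integer(0), post = integer(0), kind = character(0),
             G = numeric(0), E = numeric(0), tau = numeric(0),
             stringsAsFactors = FALSE)
}

check_conductance <- function(value, name, lo, hi) {
  if (value < 0) stop(name, " must be non-negative")
  if (value < lo || value > hi)
    warning(sprintf("%s = %g nS is outside the reference sweep range [%g, %g]",
                    name, value, lo, hi))
  value
}

#' Build the simple canonical circuit (SCC)
#'
#' Three cells: an RS source exciting both an FS interneuron and an RS target
#' through AMPA synapses, and the interneuron inhibiting the target through
#' GABA — disynaptic feedforward inhibition. The interneuron carries a 50 pA
#' holding current so a single source spike drives it to spike.
#'
#' @param g_ampa_int Src -> Int AMPA conductance (nS), default 10.
#' @param g_ampa_tgt Src -> Tgt AMPA conductance (nS), default 3
#'   (reference sweep range 1-10).
#' @param g_gaba_tgt Int -> Tgt GABA conductance (nS), default 6
#'   (reference sweep range 1-10).
#' @return An `ff_network` with neurons Src (id 1), Int (id 2), Tgt (id 3).
#' @export
build_scc <- function(g_ampa_int = 10, g_ampa_tgt = 3, g_gaba_tgt = 6) {
  check_conductance(g_ampa_tgt, "g_ampa_tgt", 1, 10)
  check_conductance(g_gaba_tgt, "g_gaba_tgt", 0, 10)
  neurons <- rbind(neuron_row(1L, "Src", 1L, "Src", 0),
                   neuron_row(2L, "Int", 1L, "Int", 50),
                   neuron_row(3L, "Tgt", 1L, "Tgt_subthreshold", 0))
  chem <- rbind(chem_row(1L, 2L, "AMPA", g_ampa_int),
                chem_row(1L, 3L, "AMPA", g_ampa_tgt),
                chem_row(2L, 3L, "GABA", g_gaba_tgt))
  elec <- data.frame(pre = integer(0), post = integer(0), G = numeric(0))
  new_ff_network("SCC", neurons, chem, elec)
}

#' Build the coupled canonical circuit (CCC)
#'
#' Two feedforward arms (Src_1 -> Int_1, Src_2 -> Int_2) converge on a single
#' shared target. The two interneurons may be coupled by a symmetric
#' electrical synapse (`g_elec`, the raw pairwise conductance, not scaled)
#' and/or reciprocal GABA synapses (`g_gaba_int` each way).
#'
#' @param g_elec Int_1 <-> Int_2 electrical conductance (nS), reference range
#'   0-8 (coupling coefficients roughly 0-0.33).
#' @param g_gaba_int Reciprocal Int <-> Int GABA conductance (nS),
#'   reference range 0-7.
#' @param g_gaba_tgt Int -> Tgt GABA conductance (nS), default 8
#'   (reference range 6-10).
#' @inheritParams build_scc
#' @return An `ff_network` with ids 1:2 = Src_1/2, 3:4 = Int_1/2, 5 = Tgt.
#' @export
build_ccc <- function(g_elec = 0, g_gaba_int = 0,
                      g_ampa_int = 10, g_ampa_tgt = 3, g_gaba_tgt = 8) {
  check_conductance(g_elec, "g_elec", 0, 8)
  check_conductance(g_gaba_int, "g_gaba_int", 0, 7)
  check_conductance(g_gaba_tgt, "g_gaba_tgt", 6, 10)
  neurons <- rbind(neuron_row(1L, "Src", 1L, "Src", 0),
                   neuron_row(2L, "Src", 2L, "Src", 0),
                   neuron_row(3L, "Int", 1L, "Int", 50),
                   neuron_row(4L, "Int", 2L, "Int", 50),
                   neuron_row(5L, "Tgt", 1L, "Tgt_subthreshold", 0))
  chem <- rbind(chem_row(1L, 3L, "AMPA", g_ampa_int),
                chem_row(2L, 4L, "AMPA", g_ampa_int),
                chem_row(1L, 5L, "AMPA", g_ampa_tgt),
                chem_row(2L, 5L, "AMPA", g_ampa_tgt),
                chem_row(3L, 5L, "GABA", g_gaba_tgt),
                chem_row(4L, 5L, "GABA", g_gaba_tgt))
  if (g_gaba_int > 0) {
    chem <- rbind(chem,
                  chem_row(3L, 4L, "GABA", g_gaba_int),
                  chem_row(4L, 3L, "GABA", g_gaba_int))
  }
  elec <- if (g_elec > 0) {
    data.frame(pre = 3L, post = 4L, G = g_elec)
  } else {
    data.frame(pre = integer(0), post = integer(0), G = numeric(0))
  }
  new_ff_network("CCC", neurons, chem, elec)
}

#' Build the coupled canonical network (CCN)
#'
#' `n_units` feedforward subunits. Within each subunit i: Src_i -> Int_i
#' (AMPA), Src_i -> Tgt_i (AMPA), Int_i -> Tgt_i (GABA); no chemical synapses
#' cross subunits. The interneuron population is coupled all-to-all by
#' electrical synapses with per-connection conductance `sum_g_elec / n_units`
#' and, when `sum_g_gaba_int > 0`, by reciprocal GABA synapses scaled the same
#' way. Targets use the network parameter variant (C = 50 pF, v_t = -45 mV)
#' and a 10 pA holding current; interneurons hold at 50 pA.
#'
#' @param n_units Number of subunits (>= 1), default 50.
#' @param sum_g_elec Summed interneuron electrical conductance (nS),
#'   reference range 0-5.
#' @param sum_g_gaba_int Summed reciprocal interneuron GABA conductance (nS),
#'   reference range 0-5.
#' @param g_ampa_int Src -> Int conductance (nS), default 5.
#' @param g_ampa_tgt Src -> Tgt conductance (nS), default 20.
#' @param g_gaba_tgt Int -> Tgt conductance (nS), default 10.
#' @return An `ff_network`; ids 1..n are Src, n+1..2n Int, 2n+1..3n Tgt.
#' @export
build_ccn <- function(n_units = 50, sum_g_elec = 0, sum_g_gaba_int = 0,
                      g_ampa_int = 5, g_ampa_tgt = 20, g_gaba_tgt = 10) {
  stopifnot(n_units >= 1)
  check_conductance(sum_g_elec, "sum_g_elec", 0, 5)
  check_conductance(sum_g_gaba_int, "sum_g_gaba_int", 0, 5)
  n <- as.integer(n_units)
  units <- seq_len(n)
  src <- units
  int <- n + units
  tgt <- 2L * n + units
  neurons <- rbind(
    do.call(rbind, lapply(units, function(i) neuron_row(src[i], "Src", i, "Src", 0))),
    do.call(rbind, lapply(units, function(i) neuron_row(int[i], "Int", i, "Int", 50))),
    do.call(rbind, lapply(units, function(i) neuron_row(tgt[i], "Tgt", i, "Tgt_network", 10))))
  chem <- rbind(chem_row(src, int, "AMPA", g_ampa_int),
                chem_row(src, tgt, "AMPA", g_ampa_tgt),
                chem_row(int, tgt, "GABA", g_gaba_tgt))
  # all-to-all interneuron coupling, self excluded, divisor stays N_Int
  if (sum_g_elec > 0 && n >= 2) {
    pairs <- t(utils::combn(int, 2))
    elec <- data.frame(pre = pairs[, 1], post = pairs[, 2],
                       G = scale_population_coupling(sum_g_elec, n))
  } else {
    elec <- data.frame(pre = integer(0), post = integer(0), G = numeric(0))
  }
  if (sum_g_gaba_int > 0 && n >= 2) {
    grid <- expand.grid(pre = int, post = int)
    grid <- grid[grid$pre != grid$post, ]
    chem <- rbind(chem, chem_row(as.integer(grid$pre), as.integer(grid$post),
                                 "GABA", scale_population_coupling(sum_g_gaba_int, n)))
  }
  new_ff_network("CCN", neurons, chem, elec)
}

#' @export
print.ff_network <- function(x, ...) {
  cat(sprintf("<ff_network %s: %d units, %d neurons, %d chemical, %d electrical>\n",
              x$config, x$n_units, nrow(x$neurons), nrow(x$chem), nrow(x$elec)))
  print(table(x$neurons$population))
  invisible(x)
}

#' Connection list of a network as a flat table
#'
#' One row per synapse (`kind` is `"AMPA"`, `"GABA"` or `"ELEC"`), suitable
#' for writing to CSV for inspection.
#'
#' @param net An `ff_network`.
#' @return A data.frame with columns `pre`, `post`, `kind`, `G`.
#' @export
connection_table <- function(net) {
  ct <- net$chem[, c("pre", "post", "kind", "G")]
  if (nrow(net$elec) > 0) {
    ct <- rbind(ct, data.frame(pre = net$elec$pre, post = net$elec$post,
                               kind = "ELEC", G = net$elec$G))
  }
  rownames(ct) <- NULL
  ct
}

neuron_ids <- function(net, population, unit = NULL) {
  sel <- net$neurons$population == population
  if (!is.null(unit)) sel <- sel & net$neurons$unit %in% unit
  net$neurons$id[sel]
}
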