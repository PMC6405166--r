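# shared fixtures: tiny networks and an R reference stepper built from the
# exported single-step primitives, used to cross-check the compiled engine

isolated_neuron_net <- function(preset = "Src", i_hold = 0) {
  p <- izhikevich_params(preset)
  net <- build_scc()
  net$neurons <- net$neurons[1, ]
  net$neurons$preset <- preset
  net$neurons$population <- "Src"
  for (f in c("C", "v_r", "v_t", "v_p", "k", "a", "b", "c", "d"))
    net$neurons[[f]] <- p[[f]]
  net$neurons$cell_type <- p$cell_type
  net$neurons$v_b <- if (is.na(p$v_b)) NA_real_ else p$v_b
  net$neurons$I_hold <- i_hold
  net$chem <- net$chem[0, ]
  net$elec <- net$elec[0, ]
  net
}

# forward-Euler reference loop in plain R, same semantics as the engine:
# currents -> state update -> gate decay -> resets -> gate increments
euler_reference <- function(net, pulses, duration, dt, v0, u0) {
  nn <- net$neurons
  n <- nrow(nn)
  plist <- lapply(seq_len(n), function(i) {
    p <- as.list(nn[i, c("cell_type", "C", "v_r", "v_t", "v_p",
                         "k", "a", "b", "c", "d", "v_b")])
    class(p) <- "izh_params"
    p
  })
  v <- v0; u <- u0
  s <- rep(0, nrow(net$chem))
  vrec <- matrix(NA_real_, round(duration / dt) + 1, n)
  vrec[1, ] <- v
  spikes <- NULL
  for (step in seq_len(round(duration / dt))) {
    t <- (step - 1) * dt
    Isyn <- rep(0, n)
    for (j in seq_len(nrow(net$chem))) {
      post <- net$chem$post[j]
      Isyn[post] <- Isyn[post] +
        chemical_current(net$chem$G[j], s[j], net$chem$E[j], v[post])
    }
    for (j in seq_len(nrow(net$elec))) {
      a <- net$elec$pre[j]; b <- net$elec$post[j]
      cur <- electrical_current(net$elec$G[j], v[a], v[b])
      Isyn[b] <- Isyn[b] + cur
      Isyn[a] <- Isyn[a] - cur
    }
    Iapp <- nn$I_hold
    for (j in seq_len(nrow(pulses))) {
      tgt <- pulses$neuron[j]
      Iapp[tgt] <- Iapp[tgt] +
        dc_pulse(pulses$amplitude[j], pulses$onset[j], pulses$duration[j], t)
    }
    v_new <- u_new <- numeric(n)
    for (i in seq_len(n)) {
      v_new[i] <- v[i] + dt * membrane_rhs(v[i], u[i], plist[[i]], Iapp[i], Isyn[i])
      u_new[i] <- u[i] + dt * recovery_rhs(v[i], u[i], plist[[i]])
    }
    v <- v_new; u <- u_new
    if (nrow(net$chem) > 0) s <- decay_gate(s, net$chem$tau, dt)
    spiked <- logical(n)
    for (i in seq_len(n)) {
      r <- apply_reset(v[i], u[i], plist[[i]])
      v[i] <- r$v; u[i] <- r$u; spiked[i] <- r$spiked
      if (r$spiked) spikes <- rbind(spikes, data.frame(neuron = i, time = step * dt))
    }
    for (j in seq_len(nrow(net$chem)))
      if (spiked[net$chem$pre[j]]) s[j] <- on_presynaptic_spike(s[j])
    vrec[step + 1, ] <- v
  }
  list(v = vrec, spikes = spikes)
}
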