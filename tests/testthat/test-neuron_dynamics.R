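test_that("parameter registry reproduces the published cell constants", {
  src <- izhikevich_params("Src")
  int <- izhikevich_params("Int")
  tgt <- izhikevich_params("Tgt_subthreshold")
  tgtn <- izhikevich_params("Tgt_network")

  expect_identical(src$cell_type, "RS")
  expect_identical(int$cell_type, "FS")
  expect_equal(unlist(src[c("C", "v_r", "v_t", "v_p", "k", "a", "b", "c", "d")]),
               c(C = 100, v_r = -60, v_t = -40, v_p = 35, k = 0.7,
                 a = 0.03, b = -2, c = -50, d = 100))
  expect_equal(unlist(int[c("C", "v_r", "v_t", "v_p", "k", "a", "b", "c", "d", "v_b")]),
               c(C = 20, v_r = -55, v_t = -40, v_p = 25, k = 1,
                 a = 0.2, b = 0.025, c = -45, d = 0, v_b = -55))
  # target variants: network version halves C and lowers the threshold
  expect_equal(c(tgt$C, tgt$v_t), c(100, -40))
  expect_equal(c(tgtn$C, tgtn$v_t), c(50, -45))
  for (p in list(src, int, tgt, tgtn)) {
    expect_lt(p$v_r, p$v_t)
    expect_lt(p$v_t, p$v_p)
    expect_lt(p$c, p$v_p)
  }
})

test_that("membrane derivative matches hand evaluations", {
  rs <- izhikevich_params("Src")
  # quadratic term vanishes at v = v_r
  expect_equal(membrane_rhs(-60, 0, rs), 0)
  # k (v-v_r)(v-v_t) / C = 0.7 * 10 * (-10) / 100
  expect_equal(membrane_rhs(-50, 0, rs), -0.7)
  # at v = v_t only the applied current survives
  for (p in list(rs, izhikevich_params("Int"))) {
    expect_equal(membrane_rhs(p$v_t, 0, p, I_app = 37), 37 / p$C)
  }
  expect_error(membrane_rhs(NaN, 0, rs), "non-finite")
})

test_that("recovery derivative matches hand evaluations for both cell classes", {
  fs <- izhikevich_params("Int")
  rs <- izhikevich_params("Src")
  # below v_b the FS drive is zero: pure decay a*(0 - u)
  expect_equal(recovery_rhs(-60, 4, fs), -0.8)
  # above v_b: a * b (v - v_b)^3 = 0.2 * 0.025 * 5^3
  expect_equal(recovery_rhs(-50, 0, fs), 0.625)
  expect_equal(recovery_rhs(rs$v_r, 0, rs), 0)
})

test_that("spike reset applies the per-type (c, d) rule only at or above v_p", {
  rs <- izhikevich_params("Src")
  fs <- izhikevich_params("Int")
  r <- apply_reset(36, 10, rs)
  expect_true(r$spiked)
  expect_equal(c(r$v, r$u), c(-50, 110))
  r <- apply_reset(26, 5, fs)  # FS d = 0: u unchanged
  expect_true(r$spiked)
  expect_equal(c(r$v, r$u), c(-45, 5))
  r <- apply_reset(0, 10, rs)
  expect_false(r$spiked)
  expect_equal(c(r$v, r$u), c(0, 10))
})

test_that("(v_r, 0) with no input is a fixed point of both equations", {
  for (preset in c("Src", "Int", "Tgt_subthreshold", "Tgt_network")) {
    p <- izhikevich_params(preset)
    expect_equal(membrane_rhs(p$v_r, 0, p), 0)
    expect_equal(recovery_rhs(p$v_r, 0, p), 0)
  }
})

test_that("an isolated RS neuron spikes periodically under sustained DC", {
  net <- isolated_neuron_net("Src")
  sim <- run_network(net, pulse_schedule(net, 50, I0 = 250, d_inp = 500),
                     duration = 600, record_v = FALSE)
  st <- sim$spikes$time
  expect_gt(length(st), 10)
  isi <- diff(st)
  late <- tail(isi, 10)  # after the adaptation transient
  expect_lt(max(late) - min(late), 0.1)
})

test_that("an isolated FS neuron at 50 pA holding settles deterministically", {
  net <- isolated_neuron_net("Int", i_hold = 50)
  s1 <- settle_network(net, t_settle = 500)
  s2 <- settle_network(net, t_settle = 500)
  expect_identical(s1, s2)
  # it rests (just below rheobase) rather than firing tonically
  sim <- run_network(net, NULL, duration = 200, record_v = FALSE, init = s1)
  expect_equal(nrow(sim$spikes), 0)
})

test_that("halving dt preserves spike counts and barely shifts spike times", {
  net <- build_scc()
  sch <- pulse_schedule(net, 50)
  cases <- list(list(net = net, sch = sch, duration = 150, dt = 0.01),
                list(net = build_ccn(1), duration = 200, dt = 0.05))
  for (cs in cases) {
    n2 <- cs$net
    sch <- pulse_schedule(n2, if (n2$config == "CCN") 100 else 50)
    s1 <- run_network(n2, sch, duration = cs$duration, dt = cs$dt, record_v = FALSE)
    s2 <- run_network(n2, sch, duration = cs$duration, dt = cs$dt / 2, record_v = FALSE)
    expect_identical(s1$spikes$neuron, s2$spikes$neuron)
    expect_lt(max(abs(s1$spikes$time - s2$spikes$time)), 2 * cs$dt)
  }
})
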