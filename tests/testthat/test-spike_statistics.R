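test_that("smoothing window is a symmetric positive raised cosine", {
  w <- hanning_window(20)
  expect_length(w, 20)
  expect_true(all(w > 0))
  expect_equal(w, rev(w))
})

test_that("density of a point mass is the window's symmetric impulse response", {
  d <- estimate_density(rep(42, 10), sigma_inp = 1)
  i <- which.max(d$d)
  span <- 8
  # the 20-bin window has even length, so the response is symmetric about a
  # half-bin offset from the mode
  expect_equal(d$d[i + seq_len(span)], d$d[i - seq_len(span) + 1],
               tolerance = 1e-9)
  # total mass = spike count x window sum
  expect_equal(sum(d$d), 10 * sum(hanning_window(20)))
})

test_that("density mass is conserved under time shifts", {
  set.seed(4)
  x <- rnorm(200, 100, 2)
  d0 <- estimate_density(x, 3)
  d5 <- estimate_density(x + 5, 3)
  expect_equal(sum(d0$d), sum(d5$d))
  expect_equal(sum(d0$d), 200 * sum(hanning_window(20)))
})

test_that("bin width tracks the input spread", {
  expect_equal(estimate_density(1:10, 5)$bin_width, 0.5)
  expect_equal(estimate_density(1:10, 1)$bin_width, 0.1)
})

test_that("distribution statistics are exact for identity and pure shifts", {
  set.seed(11)
  src <- rnorm(500, 100, 5)
  self <- distribution_stats(src, src, 5)
  expect_equal(self$norm_mean, 0)
  expect_equal(self$norm_sd, 1)
  expect_equal(self$norm_max_density, 1)
  expect_equal(self$norm_total, 1)
  expect_equal(self$rel_latency, 0)

  sh <- distribution_stats(src + 5, src, 5)
  expect_equal(sh$norm_mean, 5)
  expect_equal(sh$rel_latency, 5, tolerance = 0.5)  # bin-resolution limited
  expect_equal(sh$norm_sd, 1)
  expect_equal(sh$norm_max_density, 1, tolerance = 1e-6)
  expect_equal(sh$norm_total, 1)
})

test_that("duplicating all spikes doubles the density but not self-ratios", {
  set.seed(12)
  x <- rnorm(300, 50, 3)
  breaks <- ffinet:::density_breaks(x, 0.3, mean(x))
  d1 <- estimate_density(x, 3, breaks = breaks)
  d2 <- estimate_density(c(x, x), 3, breaks = breaks)
  expect_equal(d2$d, 2 * d1$d)
  st <- distribution_stats(c(x, x), c(x, x), 3)
  expect_equal(st$norm_max_density, 1)
  expect_equal(st$norm_total, 1)
})

test_that("gain is the difference from the uncoupled reference", {
  expect_equal(gain(3, 5), -2)
  expect_equal(gain(7.5, 7.5), 0)
  sweep <- data.frame(sigma_inp = c(1, 1, 3, 3), sum_g_elec = c(0, 2, 0, 2),
                      sum_g_gaba_int = 0, efficiency = c(100, 80, 99, 90))
  out <- add_gains(sweep, cols = "efficiency")
  expect_equal(out$gain_efficiency, c(0, -20, 0, -9))
})

test_that("response rate counts unit-trials with at least one spike", {
  raster <- data.frame(trial = c(1, 1, 2), neuron = 1, population = "Tgt",
                       unit = c(1, 2, 1), time = c(5, 6, 7))
  expect_equal(response_rate(raster, n_units = 2, n_trials = 2), 75)
  none <- raster[0, ]
  expect_equal(response_rate(none, n_units = 2, n_trials = 2), 0)
})

test_that("empty spike sets yield warnings and NA markers, not zeros", {
  expect_warning(d <- estimate_density(numeric(0), 1), "empty")
  expect_true(all(d$d == 0))
  st <- distribution_stats(numeric(0), rnorm(10, 100, 1), 1)
  expect_true(all(is.na(unlist(st))))
  expect_error(distribution_stats(1:3, numeric(0), 1), "no spikes")
})
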