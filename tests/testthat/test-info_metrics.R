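test_that("entropy matches hand-evaluated distributions", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "negative")
  expect_error(shannon_entropy(c(0.5, 0.2)), "sum")
})

test_that("joint entropy covers the canonical limits", {
  # deterministic mapping: H(joint) = H(src)
  src <- c(1, 1, 2, 2, 3, 3, 4, 4)
  tgt <- src + 7
  expect_equal(joint_spike_entropy(src, tgt, bin = 1),
               spike_time_entropy(src, bin = 1))
  # independent uniform-4 margins: additivity, 4 bits
  g <- expand.grid(a = 1:4, b = 1:4)
  expect_equal(joint_spike_entropy(g$a, g$b, bin = 1), 4)
  # 2x2 joint (0.4, 0.1; 0.1, 0.4) -> 1.721928 bits
  src <- c(rep(1, 5), rep(2, 5))
  tgt <- c(rep(1, 4), 2, 1, rep(2, 4))
  expect_equal(joint_spike_entropy(src, tgt, bin = 1), 1.721928, tolerance = 1e-6)
  expect_error(joint_spike_entropy(numeric(0), numeric(0)), "empty")
})

test_that("missing spikes are imputed with max + 2 SD of the observed set", {
  x <- c(60, 50, NA)
  expect_equal(impute_missing_spikes(x)[3], 60 + 2 * sd(c(60, 50)))
  expect_identical(impute_missing_spikes(c(4, 5)), c(4, 5))
  # fixed sentinel for demonstrations
  expect_equal(impute_missing_spikes(c(10, NA), value = 1000), c(10, 1000))
  expect_error(impute_missing_spikes(c(NA_real_, NA_real_)), "no observed")
})

test_that("mutual information attains its limits on deterministic and independent channels", {
  set.seed(20)
  src <- round(rnorm(400, 100, 5), 2)
  tgt <- src + 5.6                            # deterministic channel
  res <- mutual_information(src, tgt)
  expect_equal(res$mi, res$H_tgt, tolerance = 1e-12)
  expect_equal(res$efficiency, 100, tolerance = 1e-10)
  expect_equal(res$H_joint, res$H_src, tolerance = 1e-12)

  # independent pairing: MI collapses to plug-in bias when the sample is
  # large relative to the number of occupied bins
  srcw <- round(rnorm(2000, 100, 5))
  shuf <- mutual_information(srcw, sample(srcw + 5), bin = 1)
  expect_lt(shuf$mi / shuf$H_tgt, 0.2)
  expect_gt(shuf$mi, -1e-12)

  # symmetry of the estimator
  swapped <- mutual_information(tgt, src)
  expect_equal(res$mi, swapped$mi, tolerance = 1e-12)
})

test_that("pipeline equals a brute-force plug-in computation on a toy raster", {
  src <- c(10, 10, 11, 12, 12, 12, 13, 14, 14, 15)
  tgt <- c(20, 21, 21, 22, 22, 23, 23, 24, 24, 20)
  res <- mutual_information(src, tgt, bin = 1)
  # explicit enumeration over the joint table, independent of the pipeline
  n <- length(src)
  H <- function(p) -sum(p[p > 0] * log2(p[p > 0]))
  p_s <- as.vector(table(src)) / n
  p_t <- as.vector(table(tgt)) / n
  p_j <- as.vector(table(paste(src, tgt))) / n
  mi_brute <- H(p_s) + H(p_t) - H(p_j)
  expect_equal(res$mi, mi_brute, tolerance = 1e-12)
  expect_equal(res$efficiency, 100 * mi_brute / H(p_t), tolerance = 1e-12)
})

test_that("jittering the output never gains information (data-processing)", {
  set.seed(33)
  src <- round(rnorm(600, 100, 5), 2)
  tgt <- src + 5
  clean <- mutual_information(src, tgt, bin = 0.5)
  for (s in 1:3) {
    set.seed(s)
    jit <- mutual_information(src, tgt + rnorm(600, 0, 1), bin = 0.5)
    expect_lte(jit$mi, clean$mi + 1e-9)
  }
})

test_that("raster-level efficiency handles missing target spikes", {
  # toy raster: 2 units x 3 trials, one Tgt silent slot
  mk <- function(pop, unit, trial, time)
    data.frame(trial = trial, neuron = 1, population = pop, unit = unit,
               time = time)
  raster <- rbind(mk("Src", 1, 1:3, c(10, 11, 12)),
                  mk("Src", 2, 1:3, c(10.5, 11.5, 12.5)),
                  mk("Tgt", 1, 1:3, c(15, 16, 17)),
                  mk("Tgt", 2, 1:2, c(15.5, 16.5)))
  attr(raster, "n_units") <- 2
  attr(raster, "n_trials") <- 3
  res <- transmission_efficiency(raster)
  expect_equal(res$response_rate, 100 * 5 / 6)
  expect_true(is.finite(res$efficiency))
  # deterministic unit-latency channel with no misses scores 100%
  full <- rbind(mk("Src", 1, 1:3, c(10, 11, 12)),
                mk("Tgt", 1, 1:3, c(15, 16, 17)))
  attr(full, "n_units") <- 1
  attr(full, "n_trials") <- 3
  expect_equal(transmission_efficiency(full)$efficiency, 100)
})
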