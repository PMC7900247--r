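test_that("biexponential closed forms agree with numerical integration", {
  k <- biexp_kernel_truth(1.4, 18, 10)
  t <- seq(0, 400, by = 0.025)
  y <- ifelse(t < 0, 0, k$scale * (exp(-t / 18) - exp(-t / 1.4)))
  num_charge <- sum((y[-1] + y[-length(y)]) / 2) * 0.025
  expect_equal(num_charge, k$charge, tolerance = 1e-3)
  expect_equal(max(y), 10, tolerance = 1e-6)
  i10 <- which(y >= 1)[1]; i90 <- which(y >= 9)[1]
  expect_equal(t[i90] - t[i10], k$rise_10_90, tolerance = 0.06)
})

test_that("a noiseless event reproduces the analytic peak", {
  spec <- synthetic_spec(tau_rise = 1.4, tau_decay = 18, amplitude = 10,
                         event_times = 50, duration = 200)
  g <- gen_psc_train(spec)
  expect_equal(max(g$trace$values), 10, tolerance = 1e-6)
  expect_equal(g$truth$rise_10_90,
               biexp_kernel_truth(1.4, 18, 10)$rise_10_90)
})

test_that("Poisson event trains hit the nominal rate within 3 SE", {
  spec <- synthetic_spec(amplitude = -15, rate_hz = 3.1, duration = 180e3,
                         dt = 1, seed = 7)
  g <- gen_psc_train(spec)
  n <- nrow(g$truth)
  expected <- 3.1 * 180
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})

test_that("generation is a pure function of spec and seed", {
  spec <- synthetic_spec(amplitude = -15, rate_hz = 5, duration = 5000,
                         noise_sd = 2, seed = 123)
  g1 <- gen_psc_train(spec)
  g2 <- gen_psc_train(spec)
  expect_identical(g1$trace$values, g2$trace$values)
  expect_identical(g1$truth, g2$truth)
})

test_that("stochastic generation without a seed is refused", {
  expect_error(synthetic_spec(amplitude = 1, rate_hz = 2), "seed")
  expect_error(gen_spike_trace(c(10, 20), noise_sd = 1), "seed")
})

test_that("spike templates encode a constructible threshold", {
  g <- gen_spike_trace(spike_times = seq(20, 140, by = 20),
                       threshold_mV = -50)
  det <- detect_spikes(g$trace)
  expect_equal(length(det), 7)
  expect_equal(as.numeric(det), g$truth$peak_time, tolerance = 0.2)
  thr <- vapply(det, function(ts) as.numeric(spike_threshold(g$trace, ts)),
                numeric(1))
  expect_equal(thr, rep(-50, 7), tolerance = 0.2)
  # incompatible template
  expect_error(gen_spike_trace(10, slow_slope = 30), "criterion")
  # empty train
  g0 <- gen_spike_trace(numeric(0))
  expect_equal(nrow(g0$truth), 0)
  expect_length(detect_spikes(g0$trace), 0)
})

test_that("the Monte-Carlo release oracle converges to the recursion", {
  o1 <- stochastic_release_oracle(10, mf_presyn(), n_trials = 10000, seed = 3)
  expect_lt(abs(o1$mean - 0.6), 3 * o1$se + 1e-12)
  # exhausted pool limit: p = 1 with effectively frozen recovery
  pr <- presyn_params(1, 1e7, 5, 1e7)
  o2 <- stochastic_release_oracle(c(0, 1), pr, n_trials = 2000, seed = 4)
  expect_equal(o2$mean[1], 1)
  expect_lt(o2$mean[2], 0.01)
})
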