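test_that("integrator guards its preconditions", {
  cell <- build_grc("control")
  expect_error(integrate_cell(cell, dt = 0.1), "dt")
  expect_error(integrate_cell(cell, duration = -5), "duration")
  expect_error(integrate_cell(cell, mode = "vc"), "holding")
})

test_that("a suprathreshold step elicits repetitive firing with sane threshold", {
  res <- run_current_steps("control", steps = 10)
  tr <- res$traces[["10"]]
  sp <- detect_spikes(tr)
  sp <- sp[sp >= res$stim$t_on & sp <= res$stim$t_off]
  expect_gt(length(sp), 5)
  thr <- spike_threshold(tr, sp[1])
  expect_true(thr > -55 && thr < -40)
})

test_that("halving the time step preserves spike count and onset timing", {
  cell <- build_grc("control")
  args <- list(cell, stimulus = list(amp_pA = 10, t_on = 50, t_off = 350),
               duration = 400, i_bias_pA = 8.7, v_init = -60)
  t1 <- do.call(integrate_cell, c(args, dt = 0.025))
  t2 <- do.call(integrate_cell, c(args, dt = 0.0125))
  s1 <- detect_spikes(t1); s2 <- detect_spikes(t2)
  expect_equal(length(s1), length(s2))
  # event timing converges at first order: the first spike moves < 0.1 ms;
  # accumulated phase drift across the train stays below one interspike
  # interval (~60 us per spike at this refinement)
  expect_lt(abs(s1[1] - s2[1]), 0.1)
  expect_lt(max(abs(s1 - s2)), min(diff(s1)))
})

test_that("voltage clamp settles to a constant holding current", {
  cell <- build_grc("control")
  tr <- integrate_cell(cell, duration = 1000, mode = "vc", holding = -70)
  late <- tr$values[trace_time(tr) >= 500]
  expect_lt(max(late) - min(late), 1)   # < 1 pA drift over 500 ms
})

test_that("gating variables stay within [0, 1] throughout a firing run", {
  cell <- build_grc("sevoflurane")
  tr <- integrate_cell(cell, stimulus = list(amp_pA = 12, t_on = 50,
                                             t_off = 450),
                       duration = 500, i_bias_pA = 8, v_init = -60,
                       debug = TRUE)
  expect_true(tr$meta$gating_ok)
})
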