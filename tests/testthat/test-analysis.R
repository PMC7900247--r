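test_that("spike detection handles flat, truncated and clean traces", {
  flat <- sg_trace(rep(-70, 4000), dt = 0.025, kind = "voltage")
  expect_length(detect_spikes(flat), 0)
  g <- gen_spike_trace(spike_times = c(30, 60, 90))
  expect_length(detect_spikes(g$trace), 3)
  # trace cut in the middle of an upstroke: terminal event flagged, excluded
  tr <- g$trace
  cut <- round((90 + 2.7) / tr$dt)   # inside the fast upstroke, above -20 mV
  tr$values <- tr$values[1:cut]
  d <- detect_spikes(tr)
  expect_length(d, 2)
  expect_true(attr(d, "truncated"))
})

test_that("metric operators refuse mismatched signal kinds", {
  v <- sg_trace(rep(-70, 1000), dt = 0.025, kind = "voltage")
  i <- sg_trace(rep(0, 1000), dt = 0.025, kind = "current")
  expect_error(detect_spikes(i), "voltage")
  expect_error(psc_metrics(v, 10), "current")
  expect_error(epsp_metrics(i, 10), "voltage")
})

test_that("PSC metrics recover biexponential ground truth", {
  spec <- synthetic_spec(tau_rise = 1.4, tau_decay = 18, amplitude = -20,
                         event_times = 60, duration = 260, dt = 0.025)
  g <- gen_psc_train(spec)
  m <- psc_metrics(g$trace, 60)
  expect_equal(m$peak[1], -20, tolerance = 0.02)
  expect_lt(abs(m$tau_decay[1] - 18) / 18, 0.05)
  expect_equal(m$rise_10_90[1], g$truth$rise_10_90[1], tolerance = 0.1)
  expect_equal(m$charge[1], g$truth$charge[1], tolerance = 1)
  expect_gt(m$fit_r2[1], 0.99)
})

test_that("identical paired events give PPR one; PPR is scale invariant", {
  g <- two_event_trace()
  m <- psc_metrics(g$trace, c(60, 200))
  expect_equal(m$ppr, 1, tolerance = 0.02)
  tr2 <- g$trace; tr2$values <- tr2$values * 3.7
  m2 <- psc_metrics(tr2, c(60, 200))
  expect_equal(m2$ppr, m$ppr, tolerance = 1e-10)
  expect_equal(m2$charge, m$charge * 3.7, tolerance = 1e-9)
})

test_that("square-pulse ramp rise time follows the closed form", {
  # linear ramp of duration 10 ms: rise_10_90 is 0.8 x ramp duration
  dt <- 0.025
  t <- seq(0, 120, by = dt)
  y <- numeric(length(t))
  ramp <- t >= 40 & t < 50
  y[ramp] <- (t[ramp] - 40) / 10 * -30
  y[t >= 50] <- -30
  m <- psc_metrics(sg_trace(y, dt = dt, kind = "current"), 40)
  expect_equal(m$rise_10_90[1], 8, tolerance = 0.05)
})

test_that("EPSP metrics integrate depolarisation over the stimulus window", {
  dt <- 0.025
  k <- biexp_kernel_truth(2, 12, 5)
  t <- seq(0, 200, by = dt)
  v <- -65 + ifelse(t < 80, 0, k$scale * (exp(-(t - 80) / 12) - exp(-(t - 80) / 2)))
  m <- epsp_metrics(sg_trace(v, dt = dt, kind = "voltage"), 80)
  expect_equal(m$peak, 5, tolerance = 0.01)
  # analytic integral of the kernel over [0, 50]
  a50 <- k$scale * (12 * (1 - exp(-50 / 12)) - 2 * (1 - exp(-50 / 2)))
  expect_equal(m$area, a50, tolerance = 0.01 * a50)
  # zero trace gives zero metrics
  z <- epsp_metrics(sg_trace(rep(-65, 8001), dt = dt, kind = "voltage"), 80)
  expect_equal(z$peak, 0)
  expect_equal(z$area, 0)
  # a spike inside the window rejects the trace
  vs <- v; vs[t > 82 & t < 84] <- 20
  ms <- epsp_metrics(sg_trace(vs, dt = dt, kind = "voltage"), 80)
  expect_true(ms$rejected_spike)
  expect_true(is.na(ms$peak))
})

test_that("area and charge are exactly linear in trace scaling", {
  spec <- synthetic_spec(tau_rise = 1, tau_decay = 15, amplitude = -12,
                         event_times = 50, duration = 150, dt = 0.05)
  g <- gen_psc_train(spec)
  m1 <- psc_metrics(g$trace, 50)
  tr <- g$trace; tr$values <- tr$values * 2.5
  m2 <- psc_metrics(tr, 50)
  expect_equal(m2$charge[1], 2.5 * m1$charge[1], tolerance = 1e-9)
})

test_that("io_curve fits a line and handles the all-zero case", {
  z <- io_curve(c(10, 50, 100), c(0, 0, 0))
  expect_equal(z$slope, 0)
  io <- io_curve(c(10, 50, 100, 200), c(5, 13, 23, 43))
  f <- stats::lm(c(5, 13, 23, 43) ~ c(10, 50, 100, 200))
  expect_equal(io$slope, unname(coef(f)[2]))
  expect_error(io_curve(c(10, 20), c(1, 2, 3)))
})

test_that("condition comparison matches the textbook paired t-test", {
  idc <- compare_conditions(c(3, 4, 5), c(3, 4, 5))
  expect_equal(idc$percent_change, 0)
  expect_equal(idc$t, 0)
  ctrl <- c(10, 12, 14); trt <- c(13, 14, 18)
  cc <- compare_conditions(ctrl, trt)
  d <- trt - ctrl
  t_manual <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(cc$t, t_manual, tolerance = 1e-12)
  expect_equal(cc$percent_change, 100 * (mean(trt) - mean(ctrl)) / mean(ctrl))
  one <- compare_conditions(100, 146.3)
  expect_equal(one$percent_change, 46.3, tolerance = 1e-10)
  expect_true(one$degenerate)
  expect_true(is.na(one$p))
})
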