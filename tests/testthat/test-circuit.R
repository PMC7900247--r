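test_that("condition application is pure: identical reruns are bit-identical", {
  r1 <- run_pp_frequency_sweep("control", n_mf = 2, n_goc = 1, freqs = 50)
  r2 <- run_pp_frequency_sweep("control", n_mf = 2, n_goc = 1, freqs = 50)
  expect_identical(r1$traces[["50"]]$values, r2$traces[["50"]]$values)
  expect_identical(r1$extras$sweep, r2$extras$sweep)
})

test_that("EPSC bursts depress and sevoflurane spares the first peak", {
  rc <- run_epsc_burst("control")
  rs <- run_epsc_burst("sevoflurane")
  mc <- psc_metrics(rc$traces$clamp, rc$stim$times, sign = "negative")
  ms <- psc_metrics(rs$traces$clamp, rs$stim$times, sign = "negative")
  expect_true(all(diff(abs(mc$peak)) < 0))      # short-term depression
  expect_lt(abs(ms$peak[1] - mc$peak[1]) / abs(mc$peak[1]), 0.05)
  # residual current 50 ms after the last pulse is reduced
  resid <- function(r) {
    tr <- r$traces$clamp; tt <- trace_time(tr)
    base <- mean(tr$values[tt >= 30 & tt < 60])
    tr$values[which.min(abs(tt - (max(r$stim$times) + 50)))] - base
  }
  expect_lt(abs(resid(rs)), abs(resid(rc)))
})

test_that("the isolated NMDA current sums slowly and vanishes under sevoflurane", {
  rc <- run_nmda_isolation("control")
  rs <- run_nmda_isolation("sevoflurane")
  trc <- rc$traces$clamp; tt <- trace_time(trc)
  base <- mean(trc$values[tt >= 30 & tt < 60])
  ipk <- which.min(trc$values)
  expect_lt(trc$values[ipk] - base, -1)            # inward summation
  t_last <- max(rc$stim$times)
  expect_gt(tt[ipk], t_last + 10)                  # peak well after last pulse
  expect_lt(tt[ipk], t_last + 40)
  expect_lt(max(abs(rs$traces$clamp$values - mean(rs$traces$clamp$values))),
            1e-6)                                   # sevo: NMDA weight zero
})

test_that("IPSCs are outward at 0 mV and potentiated with a slower tail", {
  r0 <- run_ipsc_protocol("control", holding = 0)
  m0 <- psc_metrics(r0$traces$clamp, r0$stim$times)
  expect_gt(m0$peak[1], 0)
  rc <- run_ipsc_protocol("control", holding = -60)
  rs <- run_ipsc_protocol("sevoflurane", holding = -60)
  mc <- psc_metrics(rc$traces$clamp, rc$stim$times)
  ms <- psc_metrics(rs$traces$clamp, rs$stim$times)
  expect_gt(ms$peak[1], mc$peak[1])
  expect_gt(ms$tau_decay[1], mc$tau_decay[1])
})

test_that("repetitive GABA stimulation unmasks the slow spillover tail", {
  syn <- build_synapse("goc_grc")
  one <- synapse_current(syn, 60, v = -60, duration = 400, mg_mM = 0)
  train <- synapse_current(syn, seq(60, 140, by = 20), v = -60,
                           duration = 480, mg_mM = 0)
  tail_at <- function(cur, t_last, dt = 0.025) {
    idx <- round((t_last + 60) / dt) + 1L
    pk <- max(cur$trace$values)
    cur$trace$values[idx] / pk
  }
  expect_gt(tail_at(train, 140), tail_at(one, 60))
})

test_that("the mf->GoC synapse is calibrated to a -66 pA single-pulse EPSC", {
  r <- run_mf_goc_epsc("control")
  m <- psc_metrics(r$traces$clamp, r$stim$times, sign = "negative")
  expect_lt(abs(m$peak[1] - (-66)) / 66, 0.15)
})

test_that("EPSPs summate across mossy fibres and spikes are flagged", {
  r1 <- run_epsp_protocol("control", n_mf = 1)
  r3 <- run_epsp_protocol("control", n_mf = 3)
  m1 <- epsp_metrics(r1$traces$vm, r1$stim$times)
  m3 <- epsp_metrics(r3$traces$vm, r3$stim$times)
  expect_gt(m3$peak, m1$peak)
  # driving the cell hard enough produces a flagged, excluded response
  rbig <- run_epsp_protocol("control", n_mf = 4, intensity = 3)
  mbig <- epsp_metrics(rbig$traces$vm, rbig$stim$times)
  expect_true(mbig$rejected_spike)
})

test_that("the E/I grid runs clean at representative frequencies", {
  for (cond in c("control", "sevoflurane")) {
    for (nm in c(1, 4)) {
      for (ng in c(0, 4, 7)) {
        r <- run_pp_frequency_sweep(cond, n_mf = nm, n_goc = ng,
                                    freqs = c(20, 100, 200))
        expect_s3_class(r, "protocol_result")
        expect_false(any(is.na(r$extras$sweep$out_hz)))
      }
    }
  }
  expect_error(circuit_spec(n_mf = 5))
  expect_error(circuit_spec(n_goc = 8))
})
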