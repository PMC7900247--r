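test_that("Mg block is sigmoidal, exact at zero Mg, monotone in V", {
  expect_identical(mg_block(-70, 0), 1)
  expect_identical(mg_block(40, 0), 1)
  v <- seq(-90, 40, by = 5)
  b <- mg_block(v, 1.2)
  expect_true(all(diff(b) > 0))
  expect_true(all(b > 0 & b <= 1))
  # closed-form evaluation of the two-parameter block
  expect_equal(mg_block(-40, 1.2, k_conc = 3.57, k_v = 0.062),
               1 / (1 + 1.2 / 3.57 * exp(0.062 * 40)), tolerance = 1e-12)
  expect_error(mg_block(-40, -1))
})

test_that("registered receptor schemes load and are conservative", {
  for (fam in c("ampa", "nmda", "gabaa_alpha1", "gabaa_alpha6", "kainate")) {
    sch <- receptor_scheme(fam)
    expect_s3_class(sch, "receptor_scheme")
    A <- sevogranule:::scheme_generator(sch, 0.7, 0.2)
    expect_equal(unname(colSums(A)), rep(0, length(sch$states)),
                 tolerance = 1e-12)
  }
})

test_that("zero transmitter produces zero current and occupancy stays normalised", {
  sch <- receptor_scheme("ampa")
  tt <- seq(0, 50, by = 0.025)
  tm0 <- transmitter_timecourse(tt, numeric(0), numeric(0))
  r <- receptor_response(sch, tm0, v = -70, weight_nS = 1)
  expect_equal(max(abs(r$trace$values)), 0)
  tm <- transmitter_timecourse(tt, 5, 0.6)
  r2 <- receptor_response(sch, tm, v = -70, weight_nS = 1)
  expect_true(all(abs(rowSums(r2$occupancy) - 1) < 1e-9))
  expect_lt(min(r2$trace$values), 0)  # inward at -70 for E_rev = 0
})

test_that("implicit and adaptive receptor integrations agree", {
  # slow scheme: pointwise agreement of the occupancy trajectories
  nm <- receptor_scheme("nmda")
  tt <- seq(0, 120, by = 0.025)
  tm <- transmitter_timecourse(tt, c(10, 30), c(0.5, 0.4))
  ne <- receptor_response(nm, tm, v = -40, weight_nS = 1, method = "euler")
  nl <- receptor_response(nm, tm, v = -40, weight_nS = 1, method = "lsoda")
  expect_gt(max(ne$open), 0.005)
  expect_lt(max(abs(ne$open - nl$open)), 0.02 * max(ne$open))
  # fast scheme: the implicit step damps the sharp peak slightly (both
  # conditions share the bias), but the transferred charge agrees
  ga <- receptor_scheme("gabaa_alpha1")
  ge <- receptor_response(ga, tm, v = 0, weight_nS = 1, method = "euler")
  gl <- receptor_response(ga, tm, v = 0, weight_nS = 1, method = "lsoda")
  expect_lt(abs(sum(ge$open) - sum(gl$open)) / sum(gl$open), 0.02)
})

test_that("GABA current is an outward deflection at depolarised holding", {
  sch <- receptor_scheme("gabaa_alpha1")
  tt <- seq(0, 100, by = 0.025)
  tm <- transmitter_timecourse(tt, 20, 0.35)
  r <- receptor_response(sch, tm, v = 0, weight_nS = 0.5)
  expect_gt(max(r$trace$values), 0)   # chloride reversal below holding
  expect_gte(min(r$trace$values), 0)
})

test_that("spillover component is slower than the direct component", {
  tt <- seq(0, 200, by = 0.05)
  tm <- transmitter_timecourse(tt, 10, 1)
  t_dir_off <- max(tt[tm$direct > 0])
  i_sp <- which.max(tm$spill)
  half <- which(tm$spill > max(tm$spill) / 2)
  expect_gt(tt[max(half)] - tt[i_sp], t_dir_off - 10)
  expect_true(all(tm$direct >= 0) && all(tm$spill >= 0))
})
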