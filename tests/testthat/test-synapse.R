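test_that("synapse classes carry the printed presynaptic parameters", {
  mf <- build_synapse("mf_grc")
  expect_equal(mf$presyn$p, 0.6)
  expect_equal(mf$presyn$tau_rec, 8)
  expect_equal(mf$presyn$tau_facil, 5)
  expect_equal(mf$presyn$tau_i, 1)
  gg <- build_synapse("goc_grc")
  expect_equal(gg$presyn$p, 0.35)
  expect_equal(gg$presyn$tau_rec, 36)
  expect_equal(gg$presyn$tau_facil, 58.5)
  expect_equal(gg$presyn$tau_i, 0.1)
  pf <- build_synapse("pf_goc")
  expect_equal(pf$presyn$p, 0.1)
  for (k in c("mf_grc", "mf_goc", "pf_goc", "aa_goc", "goc_grc")) {
    expect_equal(build_synapse(k)$presyn$delay, 1)
  }
  expect_error(build_synapse("mf_purkinje"), "unknown synapse")
})

test_that("GoC->GrC combines fast alpha1 and slow alpha6 schemes", {
  gg <- build_synapse("goc_grc")
  fams <- vapply(gg$receptors, function(r) r$scheme$family, character(1))
  expect_setequal(fams, c("gabaa_alpha1", "gabaa_alpha6"))
})

test_that("ascending-axon conductances are about twice the parallel-fibre ones", {
  pf <- build_synapse("pf_goc")
  aa <- build_synapse("aa_goc")
  expect_equal(aa$receptors$ampa$weight_nS / pf$receptors$ampa$weight_nS, 2,
               tolerance = 0.01)
  expect_equal(aa$receptors$nmda$weight_nS / pf$receptors$nmda$weight_nS, 2,
               tolerance = 0.01)
  expect_null(aa$receptors$kainate)
  expect_false(is.null(pf$receptors$kainate))
})

test_that("the sevoflurane bundle silences NMDA at the mf->GrC synapse only", {
  mf_s <- build_synapse("mf_grc", "sevoflurane")
  mf_c <- build_synapse("mf_grc", "control")
  expect_equal(mf_s$receptors$nmda$weight_nS, 0)
  expect_equal(mf_s$receptors$ampa$weight_nS, mf_c$receptors$ampa$weight_nS)
  gg_s <- build_synapse("goc_grc", "sevoflurane")
  expect_equal(gg_s$presyn$p, 0.52)
})

test_that("condition overrides must name existing keys", {
  base <- list(a = list(b = 1), c = 2)
  expect_error(sevogranule:::apply_overrides(base, list("a.x" = 5)),
               "does not name")
  out <- sevogranule:::apply_overrides(base, list("a.b" = 5))
  expect_equal(out$a$b, 5)
  expect_match(attr(out, "override_log"), "a.b")
})

test_that("a gabazine analogue flattens the IPSC", {
  r <- run_ipsc_protocol("control", gaba_off = TRUE)
  expect_equal(max(abs(r$traces$clamp$values)), 0)
})
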