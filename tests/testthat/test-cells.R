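test_that("control GrC carries the printed densities and kinetics", {
  cell <- build_grc("control")
  tab <- channel_table(cell)
  na_h <- tab$density_S_cm2[tab$name == "na" & tab$compartment == "hillock"]
  na_a <- tab$density_S_cm2[tab$name == "na" & tab$compartment == "axon"]
  kv <- tab$density_S_cm2[tab$name == "kv"]
  expect_equal(na_h, 0.03, tolerance = 1e-9)
  expect_equal(na_a, 0.02, tolerance = 1e-9)
  expect_equal(kv, rep(0.003, 2), tolerance = 1e-9)
  kir <- tab$density_S_cm2[tab$name == "kir"]
  expect_equal(kir, 0.00135, tolerance = 1e-9)   # 1350 uS/cm2
  gab <- tab$density_S_cm2[tab$name == "gaba_leak"]
  expect_equal(unique(round(gab, 9)), 6e-5)      # 60 uS/cm2
  nap <- Filter(function(ch) ch$name == "nap", cell$spec$channels)[[1]]
  expect_equal(nap$params$Aon, 0.75)
  expect_equal(nap$params$Aoff, 0.005)
})

test_that("the sevoflurane bundle applies the printed intrinsic changes", {
  cell <- build_grc("sevoflurane")
  tab <- channel_table(cell)
  expect_equal(tab$density_S_cm2[tab$name == "na" & tab$compartment == "hillock"],
               0.04, tolerance = 1e-9)
  expect_equal(tab$density_S_cm2[tab$name == "na" & tab$compartment == "axon"],
               0.03, tolerance = 1e-9)
  expect_equal(tab$density_S_cm2[tab$name == "kv"], rep(0.005, 2),
               tolerance = 1e-9)
  nap <- Filter(function(ch) ch$name == "nap", cell$spec$channels)[[1]]
  expect_equal(nap$params$Aon, 1.5)
  expect_equal(nap$params$Aoff, 0.05)
})

test_that("unknown conditions are refused with the registered list", {
  expect_error(build_grc("desflurane"), "unknown condition")
  expect_error(build_goc("desflurane"), "unknown condition")
  expect_error(condition_set("propofol"), "control")
})

test_that("the GrC rests within 1 mV of -70 with zero current", {
  cell <- build_grc("control")
  tr <- integrate_cell(cell, duration = 500)
  expect_lt(max(abs(tr$values + 70)), 1)
  expect_length(tr$meta$spikes, 0)
})

test_that("the persistent-Na availability rises under sevoflurane", {
  # availability gate equilibrium A_off/(A_on + A_off): 0.66% -> 3.2%
  expect_equal(0.005 / 0.755, 0.0066, tolerance = 1e-2)
  expect_equal(0.05 / 1.55, 0.0323, tolerance = 1e-2)
  expect_gt((0.05 / 1.55) / (0.005 / 0.755), 4.5)
  v <- seq(-60, -40, by = 5)
  ctl <- na_steady_open("control", v)
  sev <- na_steady_open("sevoflurane", v)
  # the transient scheme itself is shared; open fractions stay finite
  expect_true(all(is.finite(c(ctl, sev))))
})

test_that("the GoC surrogate relays a mossy-fibre volley within 5 ms", {
  r <- run_pp_frequency_sweep("control", n_mf = 3, n_goc = 1, freqs = 100)
  sw <- r$extras$sweep
  expect_gte(sw$n_goc_spikes, 1)
  tr <- r$traces[["100"]]
  # GoC intrinsic parameters identical across conditions
  gc <- build_goc("control"); gs <- build_goc("sevoflurane")
  expect_identical(gc$spec$channels, gs$spec$channels)
})

test_that("temperature bounds are enforced", {
  expect_error(build_grc("control", temperature = 45), "temperature")
  expect_error(build_goc("control", temperature = 10), "temperature")
})
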