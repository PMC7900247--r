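test_that("q10 factor follows the exponential law", {
  expect_identical(q10_factor(3, 37, 37), 1)
  expect_identical(q10_factor(3, 27, 37), 3)
  expect_equal(q10_factor(2.4, 23, 30), 2.4^0.7, tolerance = 1e-12)
  expect_error(q10_factor(0, 20, 30), "positive")
  expect_error(q10_factor(-1, 20, 30), "positive")
})

test_that("q10 factor is multiplicative across temperature intervals", {
  set.seed(11)
  for (i in 1:20) {
    q <- runif(1, 1.1, 4)
    a <- runif(1, 15, 40); b <- runif(1, 15, 40); c <- runif(1, 15, 40)
    expect_equal(q10_factor(q, a, b) * q10_factor(q, b, c),
                 q10_factor(q, a, c), tolerance = 1e-12)
  }
})

test_that("the process-class table carries both Ca-diffusion variants", {
  cl <- q10_classes()
  expect_equal(cl$ionic_gating, 3)
  expect_equal(cl$receptor_gating, 2.4)
  expect_equal(cl$ionic_permeation, 1.5)
  expect_true(all(c("ca_diffusion_grc", "ca_diffusion_goc") %in% names(cl)))
})
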