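test_that("an isolated spike releases exactly p", {
  expect_equal(as.numeric(release_sequence(10, mf_presyn())), 0.6)
  expect_equal(as.numeric(release_sequence(5, gg_presyn())), 0.35)
})

test_that("zero release probability gives all-zero release", {
  pr <- presyn_params(0, 8, 5, 1)
  expect_equal(as.numeric(release_sequence(seq(0, 90, by = 10), pr)),
               rep(0, 10))
})

test_that("released fractions match an independent fine-step recursion", {
  for (pr in list(mf_presyn(), gg_presyn())) {
    st <- c(0, 20)
    expect_equal(as.numeric(release_sequence(st, pr)),
                 release_oracle(st, pr), tolerance = 1e-4)
    train <- seq(0, 180, by = 20)  # 10 pulses at 50 Hz
    expect_equal(as.numeric(release_sequence(train, pr)),
                 release_oracle(train, pr), tolerance = 1e-5)
  }
})

test_that("vesicle pools stay conserved and bounded on random trains", {
  set.seed(42)
  for (i in 1:25) {
    pr <- presyn_params(runif(1), runif(1, 2, 60), runif(1, 2, 80),
                        runif(1, 0.1, 5))
    st <- cumsum(runif(sample(2:12, 1), 1, 40))
    rel <- release_sequence(st, pr)
    expect_true(all(rel >= 0 & rel <= 1))
    s <- attr(rel, "state")
    expect_lt(abs(s$R + s$E + s$I - 1), 1e-9)
    expect_true(s$u >= 0 && s$u <= 1)
  }
})

test_that("the mossy-fibre burst shows short-term depression", {
  rel <- release_sequence(seq(0, 30, by = 10), mf_presyn())  # 4 x 100 Hz
  expect_true(all(diff(rel) <= 0))
})

test_that("non-monotone spike times are rejected", {
  expect_error(release_sequence(c(10, 5), mf_presyn()), "increasing")
})
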