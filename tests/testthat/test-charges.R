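test_that("charge normalization shifts to the target and closes the sum", {
  # already on target: identity
  cs <- normalize_charges(c(0.2, -0.2), 0)
  expect_equal(cs$q, c(0.2, -0.2))

  # correction = -0.1/3 spread uniformly
  cs <- normalize_charges(c(0.3, -0.5, 0.1), 0)
  expect_equal(cs$q, c(0.3, -0.5, 0.1) + 0.1 / 3)
  expect_equal(sum(cs$q), 0, tolerance = 1e-12)

  # charged target: correction = (-1.2 + 1)/3
  cs <- normalize_charges(c(-0.4, -0.4, -0.4), -1)
  expect_equal(cs$q, rep(-0.4 - (-1.2 + 1) / 3, 3))
  expect_equal(sum(cs$q), -1, tolerance = 1e-12)
})

test_that("charge normalization is idempotent", {
  set.seed(4)
  for (rep in 1:20) {
    q0 <- stats::rnorm(sample(2:30, 1))
    Qtg <- sample(c(-1, 0, 2), 1)
    once <- normalize_charges(q0, Qtg)$q
    twice <- normalize_charges(once, Qtg)$q
    expect_equal(twice, once, tolerance = 1e-12)
    expect_equal(sum(once), Qtg, tolerance = 1e-9)
  }
})

test_that("invalid charge input is rejected", {
  expect_error(normalize_charges(numeric(0), 0), "empty")
  expect_error(normalize_charges(c(0.1, NA), 0), "missing")
})
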