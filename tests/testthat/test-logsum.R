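test_that("the two-operand log-sum matches direct evaluation", {
  expect_equal(logsum(1, 1), 1 - log(2), tolerance = 1e-15)
  expect_equal(logsum(0, Inf), 0)
  expect_equal(logsum(Inf, 0), 0)
  expect_identical(logsum(Inf, Inf), Inf)
  expect_equal(logsum(1, 2), -log(exp(-1) + exp(-2)), tolerance = 1e-15)
  expect_equal(logsum(1, 2), 0.6867383124818, tolerance = 1e-10)
  # accurate when weights differ by many orders of magnitude
  expect_equal(logsum(0, 40), -log1p(exp(-40)), tolerance = 1e-16)
})

test_that("log-sum is commutative and bounded by its smaller operand", {
  set.seed(3)
  for (k in 1:200) {
    a <- runif(1, -30, 30); b <- runif(1, -30, 30)
    expect_identical(logsum(a, b), logsum(b, a))
    expect_lte(logsum(a, b), min(a, b))
    expect_equal(logsum(a, b), naive_logsum(c(a, b)), tolerance = 1e-13)
  }
})

test_that("logsum_fold reduces left-to-right with +Inf as empty value", {
  expect_identical(logsum_fold(numeric(0)), Inf)
  expect_identical(logsum_fold(3.5), 3.5)
  expect_equal(logsum_fold(c(0, 0, 0, 0)), -log(4), tolerance = 1e-14)
  set.seed(4)
  for (k in 1:50) {
    x <- runif(sample(2:30, 1), -20, 20)
    r <- logsum_fold(x)
    expect_equal(r, naive_logsum(x), tolerance = 1e-12)
    # permutation changes the result only at rounding level
    p <- logsum_fold(sample(x))
    expect_lt(abs(r - p), 1e-12 * abs(r) + 1e-12)
  }
  # +Inf elements are dropped exactly
  expect_identical(logsum_fold(c(Inf, 2, Inf, 1, Inf)), logsum_fold(c(2, 1)))
})
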