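test_that("a sequence with no canonical pairs has only the empty structure", {
  f <- partition_function(strrep("A", 20), toy)
  expect_true(all(is.infinite(f$V)))
  expect_equal(ensemble_free_energy(f), 0)
  expect_true(all(pair_probabilities(f) == 0))
  expect_true(all(f$W5 == 0))
  expect_true(all(f$W3 == 0))
})

test_that("the lone-hairpin sequence reproduces the two-state closed form", {
  gh <- hairpin_energy("GAAAC", 1, 5, toy)
  sigma <- exp(-gh / RT_TOY)
  f <- partition_function("GAAAC", toy)
  # V(1,5) is the hairpin energy; the exterior fragment V(5,1) is empty
  expect_equal(f$V[1, 5], gh, tolerance = 1e-12)
  expect_equal(f$V[5, 1], 0)
  expect_equal(ensemble_free_energy(f), -RT_TOY * log(1 + sigma), tolerance = 1e-12)
  expect_equal(pair_probabilities(f)[1, 5], sigma / (1 + sigma), tolerance = 1e-12)
  # w(W5'_N) accumulates 1 + sigma
  expect_equal(exp(-f$W5[6] / RT_TOY), 1 + sigma, tolerance = 1e-12)
})

test_that("staged fills continue deterministically to the one-shot result", {
  sq <- random_rna_sequence(40, seed = 12)
  s1 <- fill_interior(sq, toy)
  expect_equal(s1$stage, "interior")
  expect_null(s1$dG0)
  expect_error(ensemble_free_energy(s1), "prefix")
  expect_error(fill_exterior(s1), "prefix")
  s2 <- compute_prefix_suffix(s1)
  expect_equal(s2$stage, "prefix")
  s3 <- fill_exterior(s2)
  one <- partition_function(sq, toy)
  expect_identical(s3$V, one$V)
  expect_identical(s3$prob, one$prob)
  expect_identical(s2$W5, one$W5)
  # interior arrays are already final after stage 1
  expect_identical(s1$WQ, one$WQ)
})

test_that("the 5' and 3' accumulators agree on the total partition function", {
  for (s in 1:5) {
    sq <- random_rna_sequence(sample(20:80, 1), seed = 900 + s)
    f <- partition_function(sq, toy)
    N <- length(sq)
    w5 <- exp(-f$W5[N + 1] / RT_TOY)
    w3 <- exp(-f$W3[1] / RT_TOY)
    expect_lt(abs(w5 / w3 - 1), 1e-10)
  }
})

test_that("the fill matches the enumeration oracle on seeded short sequences", {
  # a reduced sweep; the full acceptance sweep runs in test-acceptance.R
  k <- 0
  for (L in c(6, 9, 12)) {
    for (r in 1:5) {
      k <- k + 1
      sq <- random_rna_sequence(L, c(A = .2, C = .3, G = .3, U = .2),
                                seed = 2000 + k)
      expect_fold_matches_oracle(sq, toy, cfg_full)
    }
  }
  for (r in 1:5) {
    sq <- random_rna_sequence(14, c(A = .2, C = .3, G = .3, U = .2),
                              seed = 2100 + r)
    expect_fold_matches_oracle(sq, toy, cfg_free)
  }
})

test_that("probabilities are normalized and within [0,1]", {
  for (s in 1:3) {
    sq <- random_rna_sequence(120, c(A = .2, C = .3, G = .3, U = .2),
                              seed = 950 + s)
    P <- pair_probabilities(partition_function(sq, toy))
    expect_true(all(P >= 0 & P <= 1))
    Ps <- P + t(P)
    expect_true(all(rowSums(Ps) <= 1 + 1e-6))
  }
})

test_that("rolling and full-debug storage agree bit for bit", {
  sq <- random_rna_sequence(70, seed = 77)
  a <- partition_function(sq, toy, fold_config(storage = "rolling"))
  b <- partition_function(sq, toy, fold_config(storage = "full"))
  expect_identical(a$V, b$V)
  expect_identical(a$W5, b$W5)
  expect_identical(a$W3, b$W3)
  expect_identical(a$prob, b$prob)
  # the debug mode exposes the otherwise-rolling arrays
  expect_true(all(c("W", "WL", "WMBL", "WMB") %in% names(b)))
  expect_null(a$W)
})

test_that("the weight-space reference DP and the log-space fill agree", {
  sq <- random_rna_sequence(50, seed = 21)
  rd <- reference_dp(sq, toy)
  fd <- partition_function(sq, toy)
  expect_lt(max_abs(rd$prob, fd$prob), 1e-10)
  expect_lt(abs(rd$dG0 - ensemble_free_energy(fd)), 1e-10)
})

test_that("single precision tracks double precision closely at moderate N", {
  sq <- random_rna_sequence(200, seed = 31)
  p64 <- partition_function(sq, toy)$prob
  p32 <- partition_function(sq, toy, fold_config(precision = "single"))$prob
  expect_lt(max(abs(p64 - p32)), 1e-3)
  expect_gt(rmsd_probabilities(p32, p64), 0)   # but not identical
})

test_that("the instrumented term count equals the closed form and is content-independent", {
  for (N in c(6, 10, 13)) {
    tc <- term_counter(N, cfg_full)
    f1 <- partition_function(random_rna_sequence(N, seed = 1), toy, cfg_full)
    f2 <- partition_function(strrep("A", N), toy, cfg_full)
    expect_identical(f1$term_count, tc)
    expect_identical(f2$term_count, tc)
  }
  tcf <- term_counter(10, cfg_free)
  f <- partition_function(random_rna_sequence(10, seed = 1), toy, cfg_free)
  expect_identical(f$term_count, tcf)
  # monotone in N
  counts <- vapply(4:40, term_counter, numeric(1), config = cfg_full)
  expect_true(all(diff(counts) > 0))
})

test_that("storage accounting reports the memory-reduced scheme", {
  sq <- random_rna_sequence(30, seed = 5)
  r <- storage_report(partition_function(sq, toy))
  expect_equal(r$nn_equivalents, 4.5)
  expect_equal(r$reference_equivalents, 6.0)
  expect_equal(r$reduction_pct, 25)
  rf <- storage_report(partition_function(sq, toy, fold_config(storage = "full")))
  expect_gt(rf$nn_equivalents, r$nn_equivalents)
})
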