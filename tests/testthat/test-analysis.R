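test_that("probknot keeps exactly the mutually maximal pairs", {
  P <- matrix(0, 10, 10)
  expect_equal(sum(unclass(probknot(P))), 0)       # zero matrix: all unpaired

  P[2, 9] <- 0.9
  expect_equal(structure_pairs(probknot(P, min_helix = 1)),
               cbind(i = 2L, j = 9L), ignore_attr = TRUE)

  # one mutually-maximal pair and one one-sided maximum
  Q <- matrix(0, 6, 6)
  Q[1, 4] <- 0.8          # best for 1 and for 4: kept
  Q[2, 4] <- 0.5          # best for 2, but 4 prefers 1: dropped
  st <- probknot(Q, min_helix = 1)
  expect_equal(structure_pairs(st), cbind(i = 1L, j = 4L), ignore_attr = TRUE)
  # brute-force mutual maximality over all entries agrees
  Qs <- pmax(Q, t(Q))
  for (i in 1:6) for (j in 1:6) {
    if (i < j && Qs[i, j] > 0) {
      mutual <- Qs[i, j] == max(Qs[i, ]) && Qs[i, j] == max(Qs[, j])
      expect_equal(unclass(st)[i] == j, mutual)
    }
  }

  # involution always holds, even with crossing (pseudoknotted) output
  R <- matrix(0, 12, 12)
  R[2, 8] <- 0.9; R[5, 11] <- 0.85     # crossing mutual maxima
  stR <- probknot(R, min_helix = 1)
  partner <- unclass(stR)
  paired <- which(partner > 0)
  expect_equal(partner[partner[paired]], paired)
  expect_true(rnapf:::has_pseudoknot(stR))

  # short helices are pruned at the default min_helix
  expect_equal(sum(unclass(probknot(R))), 0)
  H <- matrix(0, 12, 12)
  H[1, 12] <- .9; H[2, 11] <- .9; H[3, 10] <- .9   # 3-stack helix survives
  expect_equal(nrow(structure_pairs(probknot(H))), 3)
})

test_that("probability RMSD is averaged over all unordered pairs", {
  P <- matrix(runif(64), 8, 8)
  expect_equal(rmsd_probabilities(P, P), 0)
  expect_equal(rmsd_probabilities(P, P + 0.01), 0.01, tolerance = 1e-12)
  # two differing entries {0.1, 0.2} among the 3 pairs of N = 3
  A <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  B[1, 2] <- 0.1; B[1, 3] <- 0.2
  expect_equal(rmsd_probabilities(A, B), sqrt((0.01 + 0.04) / 3),
               tolerance = 1e-12)
  expect_error(rmsd_probabilities(matrix(0, 3, 3), matrix(0, 4, 4)), "size")
})

test_that("probability RMSD is a metric on random matrices", {
  set.seed(9)
  for (k in 1:20) {
    A <- matrix(runif(49), 7, 7); B <- matrix(runif(49), 7, 7)
    C <- matrix(runif(49), 7, 7)
    expect_equal(rmsd_probabilities(A, B), rmsd_probabilities(B, A))
    expect_lte(rmsd_probabilities(A, C),
               rmsd_probabilities(A, B) + rmsd_probabilities(B, C) + 1e-12)
  }
})

test_that("partner mismatches count every base whose assignment changed", {
  s1 <- secondary_structure(c(5L, 0L, 0L, 0L, 1L))
  expect_equal(partner_mismatch_fraction(s1, s1), list(count = 0L, fraction = 0))
  # pair (1,5) replaced by (1,4): bases 1, 4 and 5 all change partner
  s2 <- secondary_structure(c(4L, 0L, 0L, 1L, 0L))
  m <- partner_mismatch_fraction(s1, s2)
  expect_equal(m$count, 3L)
  expect_equal(m$fraction, 3 / 5)
  # fully disjoint pairings covering all bases
  a <- secondary_structure(c(2L, 1L, 4L, 3L))
  b <- secondary_structure(c(4L, 3L, 2L, 1L))
  expect_equal(partner_mismatch_fraction(a, b)$fraction, 1)
  expect_error(partner_mismatch_fraction(s1, a), "length")
})

test_that("studies are deterministic pure functions of their arguments", {
  lens <- c(30L, 60L)
  a <- precision_study(lens, seeds = 1:2, params = toy)
  b <- precision_study(lens, seeds = 1:2, params = toy)
  expect_identical(a, b)
  expect_true(all(a$value >= 0))
  expect_equal(nrow(a), 4L)
  expect_equal(unique(a$metric), "rmsd_single_vs_double")

  z <- perturbation_study(lens, seeds = 1:2, sd = 0, params = toy)
  expect_true(all(z$value == 0))
  p <- perturbation_study(lens, seeds = 1:2, sd = 0.01, params = toy)
  expect_true(all(p$value > 0))

  # the joint driver reproduces both single-study metrics exactly
  j <- accuracy_study(lens, seeds = 1:2, sd = 0.01, params = toy)
  jp <- j[j$metric == "rmsd_single_vs_double", c("length", "seed", "value")]
  rownames(jp) <- NULL
  expect_equal(jp, a[, c("length", "seed", "value")])
  jq <- j[j$metric == "rmsd_perturbed_vs_original", c("length", "seed", "value")]
  rownames(jq) <- NULL
  expect_equal(jq, p[, c("length", "seed", "value")])
})

test_that("the scaling study fits the closed-form counts", {
  s <- scaling_study(c(128L, 256L, 512L))
  expect_true(all(diff(s$value) > 0))
  expect_true(is.numeric(attr(s, "slope")))
  tmp <- tempfile(fileext = ".tsv")
  write_study_table(s, tmp)
  back <- read.delim(tmp)
  expect_equal(back$value, s$value)
  expect_equal(names(back), names(s))
})
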