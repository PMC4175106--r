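test_that("enumeration finds exactly the pseudoknot-free canonical structures", {
  expect_length(enumerate_structures("AAAA"), 1L)          # only the empty one
  st <- enumerate_structures("GAAAC")
  expect_length(st, 2L)
  np <- vapply(st, function(s) nrow(structure_pairs(s)), 0L)
  expect_setequal(np, c(0L, 1L))
  expect_equal(structure_pairs(st[[which(np == 1L)]]),
               cbind(i = 1L, j = 5L), ignore_attr = TRUE)
  expect_error(enumerate_structures(strrep("A", 20)), "cap")
})

test_that("the recursive enumerator and the counting recurrence agree", {
  for (s in 1:25) {
    sq <- random_rna_sequence(8, seed = 600 + s)
    expect_equal(length(enumerate_structures(sq)), count_structures(sq),
                 label = as.character(sq))
  }
  for (s in 1:5) {
    sq <- random_rna_sequence(13, c(A = .2, C = .3, G = .3, U = .2), seed = 700 + s)
    expect_equal(length(enumerate_structures(sq)), count_structures(sq))
  }
})

test_that("loop decomposition classifies hairpins, stacks and the exterior loop", {
  empty <- secondary_structure(integer(4))
  d <- loop_decomposition(empty, "AAAA")
  expect_length(d, 1L)
  expect_equal(d[[1]]$type, "exterior")
  expect_length(d[[1]]$branches, 0L)
  expect_equal(d[[1]]$unpaired, 4L)

  hp <- secondary_structure(c(5L, 0L, 0L, 0L, 1L))
  d <- loop_decomposition(hp, "GAAAC")
  expect_equal(vapply(d, `[[`, "", "type"), c("exterior", "hairpin"))

  # {(1,7),(2,6)} on GGAAACC: exterior + stack + hairpin
  s2 <- secondary_structure(c(7L, 6L, 0L, 0L, 0L, 2L, 1L))
  d <- loop_decomposition(s2, "GGAAACC")
  expect_setequal(vapply(d, `[[`, "", "type"), c("exterior", "stack", "hairpin"))

  pk <- secondary_structure(c(3L, 4L, 1L, 2L))   # crossing pairs
  expect_error(loop_decomposition(pk, "GCGC"), "pseudoknot")
})

test_that("structure energies are loop-decomposition sums in configuration-free mode", {
  empty <- secondary_structure(integer(5))
  expect_equal(structure_log_weight(empty, "GAAAC", toy, cfg_free), 0)
  hp <- secondary_structure(c(5L, 0L, 0L, 0L, 1L))
  expect_equal(structure_log_weight(hp, "GAAAC", toy, cfg_free),
               hairpin_energy("GAAAC", 1, 5, toy))
  s2 <- secondary_structure(c(7L, 6L, 0L, 0L, 0L, 2L, 1L))
  expect_equal(structure_log_weight(s2, "GGAAACC", toy, cfg_free),
               stack_energy("GGAAACC", 1, 7, toy) +
                 hairpin_energy("GGAAACC", 2, 6, toy))
  # full mode only adds stabilizing configuration terms for loops that
  # can host them; a lone buried hairpin with no free neighbors is equal
  expect_lte(structure_log_weight(hp, "GAAAC", toy, cfg_full),
             structure_log_weight(hp, "GAAAC", toy, cfg_free))
})

test_that("full-model exterior adornments match a hand-built configuration sum", {
  # single helix (2,6) on AGAAACA: the exterior loop can 3'-dangle base 7
  # on the branch, 5'-dangle base 1, or take the terminal mismatch
  s <- secondary_structure(c(0L, 6L, 0L, 0L, 0L, 2L, 0L))
  sq <- "AGAAACA"
  d3 <- toy$dangle3["CG", "A"]    # branch (2,6) written (6,2): pair C-G
  d5 <- toy$dangle5["CG", "A"]
  tm <- toy$multi_mismatch["CG", "A", "A"]
  w <- function(e) exp(-e / RT_TOY)
  expected <- hairpin_energy(sq, 2, 6, toy) -
    RT_TOY * log(1 + w(d3) + w(d5) + w(tm))
  expect_equal(structure_log_weight(s, sq, toy, cfg_full), expected,
               tolerance = 1e-12)
})

test_that("brute force reproduces closed forms on two-state systems", {
  bf <- brute_force_probabilities(strrep("A", 8), toy)
  expect_equal(bf$Z, 1)
  expect_true(all(bf$prob == 0))
  expect_equal(bf$dG0, 0)

  gh <- hairpin_energy("GAAAC", 1, 5, toy)
  sigma <- exp(-gh / RT_TOY)
  bf <- brute_force_probabilities("GAAAC", toy)
  expect_equal(bf$Z, 1 + sigma, tolerance = 1e-14)
  expect_equal(bf$prob[1, 5], sigma / (1 + sigma), tolerance = 1e-14)
  expect_error(brute_force_probabilities(strrep("GC", 10), toy), "cap")
})

test_that("the naive weight-space reference DP matches enumeration and reports full storage", {
  for (s in 1:5) {
    sq <- random_rna_sequence(10, seed = 800 + s)
    bf <- brute_force_probabilities(sq, toy)
    rd <- reference_dp(sq, toy)
    expect_lt(max_abs(bf$prob, rd$prob), 1e-12)
    expect_lt(abs(bf$dG0 - rd$dG0), 1e-12)
  }
  rd <- reference_dp(random_rna_sequence(30, seed = 1), toy)
  expect_gte(rd$storage_equivalents, 6.0)
  expect_equal(storage_report(rd)$nn_equivalents, 10.0)
})
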