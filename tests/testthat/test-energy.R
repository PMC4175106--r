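test_that("Boltzmann weights behave as exp(-g/RT) with a zero-weight sentinel", {
  expect_equal(boltzmann_weight(0, RT_TOY), 1)
  expect_equal(boltzmann_weight(Inf, RT_TOY), 0)
  expect_equal(boltzmann_weight(RT_TOY * log(2), RT_TOY), 0.5)
  # multiplicativity: w(g1) * w(g2) == w(g1 + g2)
  set.seed(1)
  g1 <- runif(50, -5, 5); g2 <- runif(50, -5, 5)
  expect_equal(boltzmann_weight(g1, RT_TOY) * boltzmann_weight(g2, RT_TOY),
               boltzmann_weight(g1 + g2, RT_TOY), tolerance = 1e-12)
})

test_that("hairpin energies follow initiation + first mismatch rules", {
  # size-3 loop: initiation only, read off the table independently
  expect_equal(hairpin_energy("GAAAC", 1, 5, toy),
               toy$hairpin_initiation[["3"]])
  # size-4 loop adds the first-mismatch term for the closing pair
  s <- rna_sequence("GAAAAC")
  expect_equal(hairpin_energy(s, 1, 6, toy),
               toy$hairpin_initiation[["4"]] +
                 toy$hairpin_mismatch["GC", "A", "A"])
  # below the minimum loop and non-canonical closings are forbidden
  expect_equal(hairpin_energy("GAAC", 1, 4, toy), Inf)
  expect_equal(hairpin_energy("AAAAA", 1, 5, toy), Inf)
  # beyond tabulated size 30: Jacobson-Stockmayer extrapolation
  long <- rna_sequence(paste0("G", strrep("A", 35), "C"))
  expect_equal(hairpin_energy(long, 1, 37, toy),
               toy$hairpin_initiation[["30"]] +
                 1.75 * RT_TOY * log(35 / 30) +
                 toy$hairpin_mismatch["GC", "A", "A"])
})

test_that("stack energies are table lookups with forbidden non-canonical pairs", {
  expect_equal(stack_energy("GCAAAGC", 1, 7, toy), toy$stack["GC", "CG"])
  expect_equal(stack_energy("GAAAAC", 1, 6, toy), Inf)  # inner A-A
  expect_equal(stack_energy("ACAAGU", 1, 6, toy), toy$stack["AU", "CG"])
})

test_that("internal/bulge loops: initiation, mismatches, cap, stack precondition", {
  # 1x1 internal loop: initiation(2) + both closing-pair mismatches
  s <- rna_sequence("GAGAAACAC")  # (1,9) GC around (3,7) GC, loop bases 2 and 8
  expect_equal(
    internal_energy(s, 1, 9, 3, 7, toy),
    toy$internal_initiation[["2"]] +
      toy$internal_mismatch["GC", "A", "A"] +
      toy$internal_mismatch["CG", "A", "A"]
  )
  # bulge (one side empty): initiation only
  sb <- rna_sequence("GAGAAACC")  # (1,8) GC around (3,7) GC, bulge base 2
  expect_equal(internal_energy(sb, 1, 8, 3, 7, toy),
               toy$internal_initiation[["1"]])
  # over the cap: forbidden
  big <- rna_sequence(paste0("G", strrep("A", 31), "GAAAC", "C"))
  expect_equal(internal_energy(big, 1, 38, 33, 37, toy), Inf)
  # zero unpaired is a stack, not an internal loop
  expect_error(internal_energy("GCGAAACGC", 1, 9, 2, 8, toy), "stack")
})

test_that("adornment energies follow the written-pair convention", {
  s <- rna_sequence("GAAACA")
  # dangle3 on pair (1,5) with dangling base 6
  expect_equal(adornment_energy("dangle3", s, 1, 5, 6, toy),
               toy$dangle3["GC", "A"])
  expect_equal(adornment_energy("dangle5", s, 5, 1, 2, toy),
               toy$dangle5["CG", "A"])
  expect_equal(adornment_energy("terminal_mismatch", s, 5, 1, c(6, 2), toy),
               toy$multi_mismatch["CG", "A", "A"])
  # non-canonical pair is forbidden
  expect_equal(adornment_energy("dangle3", s, 2, 3, 4, toy), Inf)
  # adjacent index outside the sequence signals "term absent"
  expect_true(is.na(adornment_energy("dangle3", s, 1, 5, 7, toy)))
  expect_true(is.na(adornment_energy("dangle5", s, 1, 5, 0, toy)))
})

test_that("coaxial energies enforce the junction geometry", {
  s <- rna_sequence("GAAACGAAAC")  # helices (1,5) and (6,10), flush at 5|6
  expect_equal(coaxial_energy("flush", s, 1, 5, 6, 10, toy),
               toy$coax_flush["GC", "GC"])
  expect_error(coaxial_energy("flush", s, 1, 5, 7, 10, toy), "adjacent")
  s2 <- rna_sequence("GAAACAGAAAC")  # gap base 6 between helices
  expect_equal(coaxial_energy("mismatch1", s2, 1, 5, 7, 11, toy),
               toy$coax_mismatch1["GC", "GC"])
  expect_equal(coaxial_energy("mismatch2", s2, 1, 5, 7, 11, toy),
               toy$coax_mismatch2["GC", "GC"])
  expect_error(coaxial_energy("mismatch1", s, 1, 5, 6, 10, toy), "gap")
  # non-canonical helix end
  s3 <- rna_sequence("GAAAAGAAAC")
  expect_equal(coaxial_energy("flush", s3, 1, 5, 6, 10, toy), Inf)
})

test_that("multibranch initiation is a + b n + c h", {
  custom <- toy
  custom$multibranch <- c(a = 10, b = 0.5, c = 1)
  expect_equal(multibranch_init(4, 3, custom), 15)
  expect_equal(multibranch_init(0, 0, custom), 10)
  custom$multibranch <- c(a = 10, b = 0, c = 0)
  expect_equal(multibranch_init(17, 9, custom), 10)
  expect_error(multibranch_init(-1, 0, toy))
})

test_that("evaluators forbid every motif with a non-canonical pair", {
  for (s in 1:20) {
    sq <- random_rna_sequence(8, seed = 500 + s)
    codes <- sq$codes
    for (i in 1:3) for (j in 6:8) {
      if (!canonical_pair(RNA_BASES[codes[i]], RNA_BASES[codes[j]])) {
        expect_identical(hairpin_energy(sq, i, j, toy), Inf)
        expect_identical(stack_energy(sq, i, j, toy), Inf)
        expect_identical(adornment_energy("dangle3", sq, i, j, 5, toy), Inf)
      }
    }
  }
})
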