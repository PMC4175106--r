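test_that("sequences are normalized, T mapped to U, and errors name the position", {
  s <- rna_sequence("gatt aca")
  expect_equal(as.character(s), "GAUUACA")
  expect_equal(length(s), 7L)
  expect_equal(s$codes, match(strsplit("GAUUACA", "")[[1]], c("A", "C", "G", "U")))

  expect_error(rna_sequence("GAXAC"), "position 3")
  expect_error(rna_sequence("GARAC"), "position 3")  # no ambiguity codes
  expect_error(rna_sequence(""), "at least one base")
})

test_that("random sequences are seeded, reproducible and composition-controlled", {
  a <- random_rna_sequence(100, seed = 42)
  b <- random_rna_sequence(100, seed = 42)
  expect_identical(as.character(a), as.character(b))
  expect_equal(length(a), 100L)
  expect_false(identical(as.character(random_rna_sequence(100, seed = 43)),
                         as.character(a)))

  # per-base frequencies within 3 standard errors of 1/4 at n = 1e5
  big <- random_rna_sequence(1e5, seed = 7)
  freq <- table(strsplit(as.character(big), "")[[1]]) / 1e5
  se <- sqrt(0.25 * 0.75 / 1e5)
  expect_true(all(abs(freq - 0.25) < 3 * se))

  # skewed composition is respected
  gc <- random_rna_sequence(1e4, c(A = 0, C = 0.5, G = 0.5, U = 0), seed = 1)
  expect_true(all(strsplit(as.character(gc), "")[[1]] %in% c("C", "G")))

  expect_error(random_rna_sequence(10, composition = c(-1, 1, 0, 0)), "non-negative")
  expect_error(random_rna_sequence(10, composition = c(0, 0, 0, 0)), "positive sum")
})

test_that("canonical pairs are Watson-Crick plus the GU wobble", {
  expect_true(canonical_pair("G", "C"))
  expect_true(canonical_pair("C", "G"))
  expect_true(canonical_pair("A", "U"))
  expect_true(canonical_pair("G", "U"))
  expect_true(canonical_pair("U", "G"))
  expect_false(canonical_pair("A", "G"))
  expect_false(canonical_pair("A", "C"))
  expect_false(canonical_pair("A", "A"))
})
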