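test_that("the packaged set is complete and validated", {
  expect_s3_class(toy, "nn_parameters")
  expect_equal(dim(toy$stack), c(6, 6))
  expect_equal(rownames(toy$stack), CANONICAL_PAIRS)
  expect_equal(names(toy$hairpin_initiation), as.character(3:30))
  expect_equal(names(toy$internal_initiation), as.character(1:30))
  expect_equal(dim(toy$hairpin_mismatch), c(6, 4, 4))
  expect_equal(dim(toy$dangle3), c(6, 4))
  expect_true(all(is.finite(toy$multibranch)))
  expect_gt(toy$temperature, 0)
  expect_equal(thermal_energy(toy), toy$gas_constant * toy$temperature)
})

test_that("the packaged stack table is rotationally self-consistent", {
  # the same physical stack read from the other strand: closing (a,b) on
  # inner (c,d) equals closing (d,c) on inner (b,a)
  flip <- c(AU = "UA", UA = "AU", GC = "CG", CG = "GC", GU = "UG", UG = "GU")
  for (p in CANONICAL_PAIRS) {
    for (q in CANONICAL_PAIRS) {
      expect_equal(toy$stack[p, q], toy$stack[flip[q], flip[p]])
    }
  }
})

test_that("schema errors name the missing or malformed table", {
  path <- tempfile(fileext = ".yaml")
  write_parameters(toy, path)
  lines <- readLines(path)

  drop_stack <- lines[!grepl("^stack:", lines)]
  # also drop the stack rows (the 6 lines after the header)
  at <- which(grepl("^stack:", lines))
  no_stack <- lines[-(at:(at + 6))]
  p2 <- tempfile(fileext = ".yaml")
  writeLines(no_stack, p2)
  expect_error(load_parameters(p2), "stack")

  bad <- sub("^  AU: \\[.*", "  AU: [a, b, c, d, e, f]", lines)
  p3 <- tempfile(fileext = ".yaml")
  writeLines(bad, p3)
  expect_error(load_parameters(p3), "non-numeric")

  expect_error(load_parameters(tempfile()), "not found")
})

test_that("load -> save -> load is the identity, including inf entries", {
  p1 <- toy
  p1$stack["AU", "GC"] <- Inf   # exercise the forbidden-entry encoding
  path <- tempfile(fileext = ".yaml")
  write_parameters(p1, path)
  p2 <- load_parameters(path)
  sections <- c(
    "stack", "hairpin_initiation", "hairpin_mismatch", "internal_initiation",
    "internal_mismatch", "dangle3", "dangle5", "multi_mismatch",
    "coax_flush", "coax_mismatch1", "coax_mismatch2", "multibranch",
    "temperature")
  for (tb in sections) {
    expect_identical(p2[[tb]], p1[[tb]], label = tb)
  }
  # a second round trip is also exact
  path2 <- tempfile(fileext = ".yaml")
  write_parameters(p2, path2)
  p3 <- load_parameters(path2)
  expect_identical(p3$stack, p2$stack)
})

test_that("parameter perturbation is seeded Gaussian noise on finite entries only", {
  expect_identical(perturb_parameters(toy, sd = 0, seed = 1)$stack, toy$stack)
  a <- perturb_parameters(toy, sd = 0.01, seed = 5)
  b <- perturb_parameters(toy, sd = 0.01, seed = 5)
  expect_identical(a, b)
  expect_false(identical(perturb_parameters(toy, sd = 0.01, seed = 6)$stack, a$stack))
  expect_false(identical(a$multibranch, toy$multibranch))
  expect_identical(a$temperature, toy$temperature)

  withinf <- toy
  withinf$stack["AU", "GC"] <- Inf
  pert <- perturb_parameters(withinf, sd = 0.01, seed = 2)
  expect_identical(pert$stack["AU", "GC"], Inf)

  # over many draws the shifts have mean ~0 and sd ~0.01 (3 SE bands)
  deltas <- unlist(lapply(1:60, function(s) {
    d <- perturb_parameters(toy, sd = 0.01, seed = 1000 + s)
    c(d$stack - toy$stack, d$dangle3 - toy$dangle3,
      d$multi_mismatch - toy$multi_mismatch,
      d$internal_mismatch - toy$internal_mismatch)
  }))
  n <- length(deltas)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(deltas)), 3 * 0.01 / sqrt(n))
  expect_lt(abs(sd(deltas) - 0.01), 3 * 0.01 / sqrt(2 * n))
})
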