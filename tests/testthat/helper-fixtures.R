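# Shared fixtures: the packaged parameter set, the configuration-free
# mode, and a tiny independent log-sum-exp evaluator used as an oracle
# for the stable log-sum.

toy <- load_parameters("toy-nn")
RT_TOY <- thermal_energy(toy)

cfg_full <- fold_config()
cfg_free <- fold_config(dangles = FALSE, terminal_mismatches = FALSE,
                        coaxial_stacking = FALSE)

# direct (naive) evaluation of -log(sum(exp(-x))); accurate enough at
# test magnitudes, independent of the package's three-branch form
naive_logsum <- function(x) {
  x <- x[is.finite(x) | x < 0]
  if (!length(x)) return(Inf)
  m <- min(x)
  m - log(sum(exp(-(x - m))))
}

# deviation helpers for DP-vs-oracle comparisons
max_abs <- function(a, b) max(abs(a - b))

expect_fold_matches_oracle <- function(seq, params, config, tol = 1e-9) {
  bf <- brute_force_probabilities(seq, params, config)
  fd <- partition_function(seq, params, config)
  expect_lt(abs(bf$dG0 - ensemble_free_energy(fd)),
            tol * thermal_energy(params))
  expect_lt(max_abs(bf$prob, fd$prob), tol)
  invisible(list(bf = bf, fd = fd))
}
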