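## Studies: ProbKnot consensus structures, probability-matrix comparison
## metrics, and the precision / perturbation / scaling experiments.

#' ProbKnot consensus structure
#'
#' Assembles a single structure from a base-pair probability matrix by
#' keeping pairs that are mutually maximal: `p[i,j]` must be the maximum
#' over all pairs involving i and over all pairs involving j.  Ties break
#' toward the smallest indices.  Additional iterations repeat the
#' selection over the still-unpaired bases.  Helices shorter than
#' `min_helix` stacked pairs are then removed.  Because mutual maximality
#' ignores nesting, the output may contain pseudoknots.
#'
#' @param P Square probability matrix (upper triangle read).
#' @param iterations Selection rounds (default 1).
#' @param min_helix Minimum helix length kept (default 3).
#' @return A [secondary_structure()] (possibly pseudoknotted).
#' @examples
#' P <- matrix(0, 10, 10); P[2, 9] <- 0.9
#' structure_pairs(probknot(P, min_helix = 1))
#' @export
probknot <- function(P, iterations = 1L, min_helix = 3L) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  N <- nrow(P)
  Ps <- pmax(P, t(P))   # symmetric view; self-pairs excluded below
  diag(Ps) <- 0
  partner <- integer(N)
  for (it in seq_len(max(1L, iterations))) {
    free <- which(partner == 0L)
    if (length(free) < 2L) break
    sub <- Ps[free, free, drop = FALSE]
    best <- integer(N)   # best[i]: smallest partner attaining max prob
    for (fi in seq_along(free)) {
      i <- free[fi]
      row <- sub[fi, ]
      mx <- max(row)
      if (mx > 0) best[i] <- free[which.max(row)]
    }
    added <- FALSE
    for (i in free) {
      j <- best[i]
      if (j > i && best[j] == i) {
        partner[i] <- j
        partner[j] <- i
        added <- TRUE
      }
    }
    if (!added) break
  }
  # prune helices shorter than min_helix (helix = maximal stacked run)
  if (min_helix > 1L) {
    seen <- logical(N)
    for (i in seq_len(N)) {
      j <- partner[i]
      if (j <= i || seen[i]) next
      run <- i
      k <- i
      while (k + 1L <= N && partner[k + 1L] == partner[k] - 1L &&
             partner[k + 1L] > k + 1L && !seen[k + 1L]) {
        k <- k + 1L
        run <- c(run, k)
      }
      seen[run] <- TRUE
      if (length(run) < min_helix) {
        partner[partner[run]] <- 0L
        partner[run] <- 0L
      }
    }
  }
  secondary_structure(partner)
}

#' RMSD between two pair-probability matrices
#'
#' Root-mean-square deviation over all unordered pairs i < j, zeros
#' included in the average.
#'
#' @param P1,P2 Square probability matrices of the same size.
#' @return Non-negative scalar.
#' @export
rmsd_probabilities <- function(P1, P2) {
  stopifnot(is.matrix(P1), is.matrix(P2))
  if (!all(dim(P1) == dim(P2))) {
    stop("probability matrices have different sizes", call. = FALSE)
  }
  up <- upper.tri(P1)
  sqrt(mean((P1[up] - P2[up])^2))
}

#' Partner disagreement between two structures
#'
#' Counts bases whose partner assignment (including "unpaired") differs
#' between two structures of the same length.
#'
#' @param s1,s2 [secondary_structure()] objects (or partner vectors).
#' @return A list with `count` and `fraction`.
#' @export
partner_mismatch_fraction <- function(s1, s2) {
  p1 <- as.integer(unclass(s1)); p2 <- as.integer(unclass(s2))
  if (length(p1) != length(p2)) {
    stop("structures have different lengths", call. = FALSE)
  }
  cnt <- sum(p1 != p2)
  list(count = cnt, fraction = cnt / length(p1))
}

.study_result <- function(rows) {
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Numerical-accuracy and scaling studies
#'
#' `precision_study()` folds each seeded random sequence in both 64-bit
#' and 32-bit arithmetic and records the RMSD between the two probability
#' matrices (`rmsd_single_vs_double`).  `perturbation_study()` folds with
#' the original and with Gaussian-perturbed parameters (sd in kcal/mol,
#' both in 64-bit) and records `rmsd_perturbed_vs_original`; the
#' perturbation seed equals the replicate seed.  `scaling_study()` records
#' the closed-form summation-term count at each length and the
#' least-squares slope of log(count) against log(N).  All studies are
#' pure functions of their arguments, so fixed seeds reproduce exactly.
#'
#' @param lengths Sequence lengths.
#' @param seeds Integer replicate seeds (one random sequence per seed).
#' @param params An `nn_parameters` set.
#' @param config Base [fold_config()] (precision/storage fields are
#'   overridden as each study requires).
#' @param composition Base composition for the random sequences.
#' @return A data frame with columns `length`, `seed`, `metric`, `value`
#'   (for `scaling_study()`: `length`, `metric`, `value` plus the fitted
#'   exponent in the `slope` attribute).
#' @export
precision_study <- function(lengths = c(100L, 200L, 400L, 800L),
                            seeds = 1:10,
                            params = load_parameters("toy-nn"),
                            config = fold_config(),
                            composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  cfg64 <- modifyList(config, list(precision = "double"))
  class(cfg64) <- "fold_config"
  cfg32 <- modifyList(config, list(precision = "single"))
  class(cfg32) <- "fold_config"
  rows <- list()
  for (L in lengths) {
    for (sd_ in seeds) {
      sq <- random_rna_sequence(L, composition, seed = sd_)
      P64 <- partition_function(sq, params, cfg64)$prob
      P32 <- partition_function(sq, params, cfg32)$prob
      rows[[length(rows) + 1L]] <- data.frame(
        length = L, seed = sd_, metric = "rmsd_single_vs_double",
        value = rmsd_probabilities(P32, P64)
      )
    }
  }
  .study_result(rows)
}

#' @rdname precision_study
#' @param sd Parameter perturbation standard deviation, kcal/mol.
#' @export
perturbation_study <- function(lengths = c(100L, 200L, 400L, 800L),
                               seeds = 1:10,
                               sd = 0.01,
                               params = load_parameters("toy-nn"),
                               config = fold_config(),
                               composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  cfg64 <- modifyList(config, list(precision = "double"))
  class(cfg64) <- "fold_config"
  rows <- list()
  for (L in lengths) {
    for (sd_ in seeds) {
      sq <- random_rna_sequence(L, composition, seed = sd_)
      P0 <- partition_function(sq, params, cfg64)$prob
      Pp <- partition_function(sq, perturb_parameters(params, sd = sd, seed = sd_),
                               cfg64)$prob
      rows[[length(rows) + 1L]] <- data.frame(
        length = L, seed = sd_, metric = "rmsd_perturbed_vs_original",
        value = rmsd_probabilities(Pp, P0)
      )
    }
  }
  .study_result(rows)
}

#' @rdname precision_study
#' @details `accuracy_study()` is the joint driver: for each (length,
#' seed) it folds once in double precision, once in single precision and
#' once with perturbed parameters, and records both RMSD metrics from the
#' shared double-precision reference — the same quantities as running
#' [precision_study()] and [perturbation_study()], at one-third fewer
#' fills.
#' @export
accuracy_study <- function(lengths = c(100L, 200L, 400L, 800L),
                           seeds = 1:10,
                           sd = 0.01,
                           params = load_parameters("toy-nn"),
                           config = fold_config(),
                           composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  cfg64 <- modifyList(config, list(precision = "double"))
  class(cfg64) <- "fold_config"
  cfg32 <- modifyList(config, list(precision = "single"))
  class(cfg32) <- "fold_config"
  rows <- list()
  for (L in lengths) {
    for (sd_ in seeds) {
      sq <- random_rna_sequence(L, composition, seed = sd_)
      P64 <- partition_function(sq, params, cfg64)$prob
      P32 <- partition_function(sq, params, cfg32)$prob
      Pp <- partition_function(sq, perturb_parameters(params, sd = sd, seed = sd_),
                               cfg64)$prob
      rows[[length(rows) + 1L]] <- data.frame(
        length = L, seed = sd_,
        metric = c("rmsd_single_vs_double", "rmsd_perturbed_vs_original"),
        value = c(rmsd_probabilities(P32, P64), rmsd_probabilities(Pp, P64))
      )
    }
  }
  .study_result(rows)
}

#' @rdname precision_study
#' @export
scaling_study <- function(lengths = c(512L, 1024L, 2048L, 4096L),
                          config = fold_config()) {
  stopifnot(length(lengths) >= 3L)
  counts <- vapply(lengths, term_counter, numeric(1), config = config)
  fit <- lm(log(counts) ~ log(as.numeric(lengths)))
  out <- data.frame(length = lengths, metric = "term_count", value = counts)
  attr(out, "slope") <- unname(coef(fit)[2L])
  out
}

#' Write a study table as TSV
#'
#' Tab-separated, header line first; the standard interchange format for
#' the study results.
#'
#' @param df A study data frame.
#' @param path Output path.
#' @export
write_study_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
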