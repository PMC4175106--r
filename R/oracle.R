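## Ground-truth machinery: exhaustive enumeration of pseudoknot-free
## structures, nearest-neighbor loop decomposition, per-structure
## Boltzmann weights (with the full adornment-configuration sum), and
## brute-force partition functions / pair probabilities.  Everything here
## is independent of the dynamic program: weights come from the loop
## decomposition and the R energy evaluators, so agreement with the DP is
## a genuine two-route check.

#' Exhaustively enumerate pseudoknot-free structures
#'
#' All sets of canonical, non-crossing pairs whose hairpin loops respect
#' the minimum loop size, including the empty structure.  Intended for
#' short sequences; `N > cap` is refused.
#'
#' @param seq An [rna_sequence()] or string.
#' @param config A [fold_config()] (supplies the minimum hairpin size).
#' @param cap Refusal threshold on sequence length (default 16).
#' @return List of [secondary_structure()] objects (no duplicates).
#' @examples
#' length(enumerate_structures("AAAA"))   # 1: only the empty structure
#' length(enumerate_structures("GAAAC"))  # 2: empty and {(1,5)}
#' @export
enumerate_structures <- function(seq, config = fold_config(), cap = 16L) {
  seq <- as_rna_sequence(seq)
  N <- length(seq)
  if (N > cap) {
    stop(sprintf("enumeration refused: N = %d exceeds the cap of %d bases", N, cap),
         call. = FALSE)
  }
  codes <- seq$codes
  minhp <- config$min_hairpin
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (j - i + 1 < minhp + 2) return(list(integer(0)))
    key <- paste0(i, ":", j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- gen(i + 1L, j)  # i unpaired
    for (k in (i + minhp + 1L):j) {
      if (PAIR_CODE[codes[i], codes[k]] == 0L) next
      left <- gen(i + 1L, k - 1L)
      right <- if (k + 1L <= j) gen(k + 1L, j) else list(integer(0))
      for (s1 in left) for (s2 in right) {
        out[[length(out) + 1L]] <- c(i, k, s1, s2)
      }
    }
    memo[[key]] <- out
    out
  }
  pairsets <- gen(1L, N)
  lapply(pairsets, function(ps) {
    partner <- integer(N)
    if (length(ps)) {
      m <- matrix(ps, nrow = 2L)
      partner[m[1L, ]] <- m[2L, ]
      partner[m[2L, ]] <- m[1L, ]
    }
    secondary_structure(partner)
  })
}

#' @rdname enumerate_structures
#' @details `count_structures()` evaluates the number of pseudoknot-free
#' structures by an independent interval-counting recurrence (no
#' structure lists are built), providing a cross-check on the enumerator
#' and a way to count for longer sequences.
#' @export
count_structures <- function(seq, config = fold_config()) {
  seq <- as_rna_sequence(seq)
  codes <- seq$codes
  N <- length(seq)
  minhp <- config$min_hairpin
  # C[i, j]: structure count on interval i..j (1 when the interval is
  # too short to hold a pair); filled by increasing interval length
  C <- matrix(1, N + 1L, N + 1L)
  if (N >= minhp + 2L) {
    for (len in (minhp + 2L):N) {
      for (i in 1:(N - len + 1L)) {
        j <- i + len - 1L
        tot <- C[i + 1L, j]
        for (k in (i + minhp + 1L):j) {
          if (PAIR_CODE[codes[i], codes[k]] == 0L) next
          left <- if (k - 1L >= i + 1L) C[i + 1L, k - 1L] else 1
          right <- if (k + 1L <= j) C[k + 1L, j] else 1
          tot <- tot + left * right
        }
        C[i, j] <- tot
      }
    }
  }
  C[1L, N]
}

#' Nearest-neighbor loop decomposition
#'
#' Decomposes a pseudoknot-free structure into its loops: one exterior
#' loop plus, for every pair, the loop it closes inward (hairpin, stack,
#' internal/bulge, or multibranch).
#'
#' @param structure A [secondary_structure()].
#' @param seq The sequence (used only for length validation).
#' @return A list of loop records: `type`, `closing` (c(i,j) or NULL for
#'   the exterior loop), `branches` (list of c(p,q) in 5'-to-3' order) and
#'   `unpaired` (count of unpaired bases in the loop).
#' @export
loop_decomposition <- function(structure, seq) {
  seq <- as_rna_sequence(seq)
  partner <- unclass(structure)
  N <- length(partner)
  stopifnot(N == length(seq))
  if (has_pseudoknot(structure)) {
    stop("pseudoknotted structures have no nearest-neighbor loop decomposition",
         call. = FALSE)
  }
  children <- function(i, j) {
    out <- list()
    k <- i
    while (k <= j) {
      if (partner[k] > k && partner[k] <= j) {
        out[[length(out) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else {
        k <- k + 1L
      }
    }
    out
  }
  span <- function(br) if (length(br)) sum(vapply(br, function(b) b[2] - b[1] + 1L, 0L)) else 0L
  ext <- children(1L, N)
  loops <- list(list(type = "exterior", closing = NULL, branches = ext,
                     unpaired = N - span(ext)))
  for (i in which(partner > seq_len(N))) {
    j <- partner[i]
    ch <- if (i + 1L <= j - 1L) children(i + 1L, j - 1L) else list()
    unp <- (j - i - 1L) - span(ch)
    type <- if (length(ch) == 0L) {
      "hairpin"
    } else if (length(ch) == 1L && ch[[1L]][1L] == i + 1L && ch[[1L]][2L] == j - 1L) {
      "stack"
    } else if (length(ch) == 1L) {
      "internal"
    } else {
      "multibranch"
    }
    loops[[length(loops) + 1L]] <- list(type = type, closing = c(i, j),
                                        branches = ch, unpaired = unp)
  }
  loops
}

## Sum over adornment configurations of one multibranch or exterior loop,
## in Boltzmann-weight space (configuration energies only; the loop's
## a/b/c constants are handled by the caller).  Each branch end takes at
## most one of {nothing, 3' dangle, 5' dangle, terminal mismatch, coaxial
## stack with an adjacent branch}; each unpaired base serves at most one
## adornment; each helix joins at most one coaxial stack; the closing
## pair of a multibranch loop may coax with the first or last branch.
## The open exterior loop (closing = NULL) carries no coaxial stacking.
adorn_config_sum <- function(codes, params, config, branches, avail, closing, RTv) {
  N <- length(codes)
  m <- length(branches)
  if (m == 0L) return(1)
  wE <- function(E) exp(-E / RTv)
  pidx <- function(x, y) PAIR_CODE[codes[x], codes[y]]
  lk_d3 <- function(x, y, z) {
    p <- pidx(x, y); if (p == 0L) Inf else params$dangle3[p, codes[z]]
  }
  lk_d5 <- function(x, y, z) {
    p <- pidx(x, y); if (p == 0L) Inf else params$dangle5[p, codes[z]]
  }
  lk_tm <- function(x, y, u, v) {
    p <- pidx(x, y); if (p == 0L) Inf else params$multi_mismatch[p, codes[u], codes[v]]
  }
  lk_cx <- function(kind, A, B) {
    p <- pidx(A[1], A[2]); q <- pidx(B[1], B[2])
    if (p == 0L || q == 0L) return(Inf)
    switch(kind,
           flush = params$coax_flush[p, q],
           mm1 = params$coax_mismatch1[p, q],
           mm2 = params$coax_mismatch2[p, q])
  }
  ok <- function(x, consumed) {
    x >= 1L && x <= N && (x %in% avail) && !(x %in% consumed)
  }
  # coax options between written tuples A, B with the junction after A[2];
  # mm1 additionally consumes the base 5' of A, mm2 the base 3' of B
  coax_opts <- function(A, B, consumed) {
    opts <- list()
    if (B[1] == A[2] + 1L) {
      opts[[1L]] <- list(w = wE(lk_cx("flush", A, B)), consumed = integer(0))
    } else if (B[1] == A[2] + 2L) {
      g <- A[2] + 1L
      if (ok(g, consumed) && ok(A[1] - 1L, c(consumed, g))) {
        opts[[length(opts) + 1L]] <-
          list(w = wE(lk_cx("mm1", A, B)), consumed = c(g, A[1] - 1L))
      }
      if (ok(g, consumed) && ok(B[2] + 1L, c(consumed, g))) {
        opts[[length(opts) + 1L]] <-
          list(w = wE(lk_cx("mm2", A, B)), consumed = c(g, B[2] + 1L))
      }
    }
    opts
  }
  chain <- function(t, consumed, lastc) {
    if (t > lastc) return(1)
    B <- branches[[t]]
    p <- B[1]; q <- B[2]
    tot <- chain(t + 1L, consumed, lastc)
    if (config$dangles) {
      if (ok(q + 1L, consumed)) {
        tot <- tot + wE(lk_d3(q, p, q + 1L)) * chain(t + 1L, c(consumed, q + 1L), lastc)
      }
      if (ok(p - 1L, consumed)) {
        tot <- tot + wE(lk_d5(q, p, p - 1L)) * chain(t + 1L, c(consumed, p - 1L), lastc)
      }
    }
    if (config$terminal_mismatches && ok(q + 1L, consumed) && ok(p - 1L, c(consumed, q + 1L))) {
      tot <- tot + wE(lk_tm(q, p, q + 1L, p - 1L)) *
        chain(t + 1L, c(consumed, q + 1L, p - 1L), lastc)
    }
    if (config$coaxial_stacking && !is.null(closing) && t + 1L <= lastc) {
      for (op in coax_opts(branches[[t]], branches[[t + 1L]], consumed)) {
        tot <- tot + op$w * chain(t + 2L, c(consumed, op$consumed), lastc)
      }
    }
    tot
  }
  if (is.null(closing)) return(chain(1L, integer(0), m))
  i <- closing[1]; j <- closing[2]
  states <- list(list(w = 1, consumed = integer(0), first = 1L, lastc = m))
  if (config$dangles) {
    if (ok(i + 1L, integer(0))) {
      states <- c(states, list(list(w = wE(lk_d3(i, j, i + 1L)),
                                    consumed = i + 1L, first = 1L, lastc = m)))
    }
    if (ok(j - 1L, integer(0))) {
      states <- c(states, list(list(w = wE(lk_d5(i, j, j - 1L)),
                                    consumed = j - 1L, first = 1L, lastc = m)))
    }
  }
  if (config$terminal_mismatches && ok(i + 1L, integer(0)) && ok(j - 1L, i + 1L)) {
    states <- c(states, list(list(w = wE(lk_tm(i, j, i + 1L, j - 1L)),
                                  consumed = c(i + 1L, j - 1L), first = 1L, lastc = m)))
  }
  if (config$coaxial_stacking) {
    for (op in coax_opts(c(j, i), branches[[1L]], integer(0))) {
      states <- c(states, list(list(w = op$w, consumed = op$consumed,
                                    first = 2L, lastc = m)))
    }
    for (op in coax_opts(branches[[m]], c(j, i), integer(0))) {
      states <- c(states, list(list(w = op$w, consumed = op$consumed,
                                    first = 1L, lastc = m - 1L)))
    }
  }
  tot <- 0
  for (st in states) tot <- tot + st$w * chain(st$first, st$consumed, st$lastc)
  tot
}

#' Free energy of a single structure
#'
#' The structure's standard free energy relative to the all-unpaired
#' state, from its loop decomposition.  Hairpin, stack and internal loops
#' contribute their evaluator energies.  A multibranch loop with `h`
#' helices and `n` unpaired bases contributes \eqn{a + b n + c h} plus, in
#' the full model, \eqn{-RT \log} of the sum over its adornment
#' configurations (dangles, terminal mismatches, coaxial stacks); the
#' exterior loop likewise contributes its configuration sum but no
#' initiation constants.  In configuration-free mode every adornment sum
#' is 1 and the energy is the plain loop-decomposition sum.
#'
#' @inheritParams loop_decomposition
#' @param params An `nn_parameters` set.
#' @param config A [fold_config()].
#' @return Free energy in kcal/mol; `+Inf` if any loop is forbidden; the
#'   empty structure has energy 0.
#' @export
structure_log_weight <- function(structure, seq, params, config = fold_config()) {
  seq <- as_rna_sequence(seq)
  codes <- seq$codes
  RTv <- thermal_energy(params)
  partner <- unclass(structure)
  loops <- loop_decomposition(structure, seq)
  G <- 0
  for (lp in loops) {
    g <- switch(lp$type,
      exterior = {
        avail <- setdiff(seq_along(partner), unlist(lapply(lp$branches, function(b) b[1]:b[2])))
        s <- adorn_config_sum(codes, params, config, lp$branches, avail, NULL, RTv)
        -RTv * log(s)
      },
      hairpin = hairpin_energy(seq, lp$closing[1], lp$closing[2], params, config),
      stack = stack_energy(seq, lp$closing[1], lp$closing[2], params),
      internal = internal_energy(seq, lp$closing[1], lp$closing[2],
                                 lp$branches[[1]][1], lp$branches[[1]][2],
                                 params, config),
      multibranch = {
        i <- lp$closing[1]; j <- lp$closing[2]
        inside <- (i + 1L):(j - 1L)
        avail <- setdiff(inside, unlist(lapply(lp$branches, function(b) b[1]:b[2])))
        s <- adorn_config_sum(codes, params, config, lp$branches, avail,
                              lp$closing, RTv)
        multibranch_init(lp$unpaired, length(lp$branches) + 1L, params) -
          RTv * log(s)
      }
    )
    G <- G + g
    if (!is.finite(G)) return(Inf)
  }
  G
}

#' Brute-force partition function and pair probabilities
#'
#' Literal evaluation of the ensemble: enumerate every pseudoknot-free
#' structure, weight each by `exp(-G/RT)` from [structure_log_weight()],
#' sum for Z and accumulate weighted pair frequencies.  The ground truth
#' against which the dynamic program is validated.
#'
#' @inheritParams enumerate_structures
#' @param params An `nn_parameters` set.
#' @return A list: `structures`, `energies` (kcal/mol), `Z` (relative to
#'   the all-unpaired state), `dG0` (`-RT log Z`), and `prob` (N-by-N
#'   matrix, upper triangle).
#' @examples
#' p <- load_parameters("toy-nn")
#' bf <- brute_force_probabilities("GAAAC", p)
#' bf$prob[1, 5]   # sigma / (1 + sigma) for the lone hairpin
#' @export
brute_force_probabilities <- function(seq, params, config = fold_config(), cap = 16L) {
  seq <- as_rna_sequence(seq)
  N <- length(seq)
  if (N > cap) {
    stop(sprintf("brute force refused: N = %d exceeds the cap of %d bases", N, cap),
         call. = FALSE)
  }
  structs <- enumerate_structures(seq, config, cap)
  RTv <- thermal_energy(params)
  G <- vapply(structs, function(s) structure_log_weight(s, seq, params, config),
              numeric(1))
  w <- exp(-G / RTv)
  Z <- sum(w)
  P <- matrix(0, N, N)
  for (si in seq_along(structs)) {
    pr <- structure_pairs(structs[[si]])
    if (nrow(pr)) P[pr] <- P[pr] + w[si]
  }
  P <- P / Z
  list(structures = structs, energies = G, Z = Z, dG0 = -RTv * log(Z), prob = P)
}

#' Naive weight-space reference dynamic program
#'
#' The same recursions as [partition_function()], evaluated directly on
#' Boltzmann weights with every array stored as a full N-by-N matrix (ten
#' full-array equivalents) and no scaling factors.  Valid only while
#' 64-bit weights do not overflow; overflow raises an error — the
#' documented limitation that motivates the log-space production fill.
#'
#' @inheritParams brute_force_probabilities
#' @return A list with `Z`, `dG0`, `prob`, `V_weight` (the V array as
#'   weights) and `storage_equivalents` (10.0).
#' @export
reference_dp <- function(seq, params, config = fold_config()) {
  seq <- as_rna_sequence(seq)
  res <- .cpp_reference_dp(seq$codes, pack_tables(params), unclass(config))
  res$seq <- seq
  class(res) <- "reference_dp"
  res
}
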