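## Per-loop free-energy evaluators (R side).
##
## These are the module-level reference implementations: the exhaustive
## enumeration oracle is built on them, and the C++ fill carries an
## independent mirror of the same lookup conventions.  Positions are
## 1-based; every lookup is written "pair as seen from the loop, then the
## loop-adjacent bases", matching the recursion subscripts:
##   dangle3(x, y, z):  pair (x,y), dangling base z = x+1
##   dangle5(x, y, z):  pair (x,y), dangling base z = y-1
##   tm(x, y, u, v):    pair (x,y), mismatch bases u = x+1, v = y-1
## A loop sees its closing pair (i,j) as (i,j) and an inner branch (p,q)
## as (q,p); with that orientation the same three rules cover every case.

.pidx <- function(codes, x, y) PAIR_CODE[codes[x], codes[y]]

#' Boltzmann weight of a free energy
#'
#' \eqn{w(g) = \exp(-g/RT)}; the sentinel `+Inf` ("forbidden motif") maps
#' to weight 0.  Vectorized over `g`.
#'
#' @param g Free energy (kcal/mol); `+Inf` allowed.
#' @param RT Thermal energy in kcal/mol (> 0).
#' @return Non-negative weight(s).
#' @examples
#' boltzmann_weight(0, 0.6)                    # 1
#' boltzmann_weight(Inf, 0.6)                  # 0
#' boltzmann_weight(0.6 * log(2), 0.6)         # 0.5
#' @export
boltzmann_weight <- function(g, RT) {
  stopifnot(RT > 0)
  exp(-g / RT)
}

#' Hairpin loop free energy
#'
#' Initiation by loop size (tabulated 3..30; larger loops extrapolate as
#' \eqn{\Delta G(30) + 1.75\,RT\log(n/30)}) plus a first-mismatch term for
#' loops of size >= 4.  Returns `+Inf` when (i,j) is not canonical or the
#' loop is shorter than the minimum hairpin size.
#'
#' @param seq An [rna_sequence()] (or string).
#' @param i,j Closing pair positions, `1 <= i < j <= N`.
#' @param params An `nn_parameters` set.
#' @param config A [fold_config()].
#' @return Free energy in kcal/mol (possibly `+Inf`).
#' @export
hairpin_energy <- function(seq, i, j, params, config = fold_config()) {
  seq <- as_rna_sequence(seq)
  codes <- seq$codes
  n <- length(codes)
  stopifnot(1 <= i, i < j, j <= n)
  p <- .pidx(codes, i, j)
  loop <- j - i - 1L
  if (p == 0L || loop < config$min_hairpin) return(Inf)
  init <- if (loop < 3L) {
    Inf  # below the tabulated range (only reachable with min_hairpin < 3)
  } else if (loop <= 30L) {
    params$hairpin_initiation[[as.character(loop)]]
  } else {
    params$hairpin_initiation[["30"]] +
      1.75 * thermal_energy(params) * log(loop / 30)
  }
  mm <- if (loop >= 4L) params$hairpin_mismatch[p, codes[i + 1L], codes[j - 1L]] else 0
  init + mm
}

#' Helix stack free energy
#'
#' Table entry for closing pair (i,j) stacked on inner pair (i+1,j-1);
#' `+Inf` if either pair is non-canonical.
#'
#' @inheritParams hairpin_energy
#' @export
stack_energy <- function(seq, i, j, params) {
  seq <- as_rna_sequence(seq)
  codes <- seq$codes
  stopifnot(1 <= i, i + 1 < j - 1, j <= length(codes))
  p <- .pidx(codes, i, j)
  q <- .pidx(codes, i + 1L, j - 1L)
  if (p == 0L || q == 0L) return(Inf)
  params$stack[p, q]
}

#' Internal/bulge loop free energy
#'
#' Closing pair (i,j) around inner pair (ip,jp) with `i < ip < jp < j` and
#' at least one unpaired base.  Energy is the initiation for the total
#' unpaired size plus, for true internal loops (both sides >= 1), one
#' terminal-mismatch term per closing pair; bulges get initiation only.
#' Loops whose total unpaired size exceeds the configured cap are
#' forbidden (`+Inf`), as are non-canonical pairs.  The zero-unpaired
#' motif `(ip,jp) = (i+1,j-1)` is a stack, not an internal loop, and is a
#' precondition error.
#'
#' @param ip,jp Inner pair positions.
#' @inheritParams hairpin_energy
#' @export
internal_energy <- function(seq, i, j, ip, jp, params, config = fold_config()) {
  seq <- as_rna_sequence(seq)
  codes <- seq$codes
  stopifnot(1 <= i, i < ip, ip < jp, jp < j, j <= length(codes))
  n1 <- ip - i - 1L
  n2 <- j - jp - 1L
  if (n1 + n2 < 1L) {
    stop("zero unpaired bases: (ip,jp) = (i+1,j-1) is a stack, not an internal loop",
         call. = FALSE)
  }
  if (n1 + n2 > config$internal_loop_cap) return(Inf)
  p <- .pidx(codes, i, j)
  q <- .pidx(codes, ip, jp)
  if (p == 0L || q == 0L) return(Inf)
  if (n1 + n2 > 30L) return(Inf)  # tabulated range; cap defaults to 30 anyway
  g <- params$internal_initiation[[as.character(n1 + n2)]]
  if (n1 >= 1L && n2 >= 1L) {
    qr <- .pidx(codes, jp, ip)  # inner pair as seen from the loop
    g <- g + params$internal_mismatch[p,  codes[i + 1L],  codes[j - 1L]] +
             params$internal_mismatch[qr, codes[jp + 1L], codes[ip - 1L]]
  }
  g
}

#' Dangling-end and terminal-mismatch free energies
#'
#' Looks up the adornment energy for a helix-end pair written as `(x,y)`
#' from the loop's perspective: `dangle3` stacks base `x+1`, `dangle5`
#' stacks base `y-1`, `terminal_mismatch` stacks both.  `adjacent` gives
#' the dangling/mismatch base position(s) explicitly; a position outside
#' `1..N` signals "term absent" by returning `NA`, which callers treat as
#' dropping the term.  A non-canonical `(x,y)` returns `+Inf`.
#'
#' @param kind One of `"dangle3"`, `"dangle5"`, `"terminal_mismatch"`.
#' @param x,y Helix-end pair positions as seen from the loop.
#' @param adjacent Integer position(s): one base for dangles, two
#'   (`c(x+1, y-1)`) for a terminal mismatch.
#' @inheritParams hairpin_energy
#' @return Energy in kcal/mol, `+Inf` for a non-canonical pair, or `NA`
#'   when an adjacent position falls outside the sequence.
#' @export
adornment_energy <- function(kind = c("dangle3", "dangle5", "terminal_mismatch"),
                             seq, x, y, adjacent, params) {
  kind <- match.arg(kind)
  seq <- as_rna_sequence(seq)
  codes <- seq$codes
  n <- length(codes)
  stopifnot(x >= 1, x <= n, y >= 1, y <= n, x != y)
  if (any(adjacent < 1 | adjacent > n)) return(NA_real_)
  if (any(adjacent == x | adjacent == y)) {
    stop("adjacent bases must be distinct from the pair", call. = FALSE)
  }
  p <- .pidx(codes, x, y)
  if (p == 0L) return(Inf)
  switch(kind,
    dangle3 = params$dangle3[p, codes[adjacent[1L]]],
    dangle5 = params$dangle5[p, codes[adjacent[1L]]],
    terminal_mismatch = {
      stopifnot(length(adjacent) == 2L)
      params$multi_mismatch[p, codes[adjacent[1L]], codes[adjacent[2L]]]
    }
  )
}

#' Coaxial stacking free energies
#'
#' Stacking of two helix ends in a multibranch loop, written as helices
#' `(a,b)` and `(c,d)` in loop order.  `flush` requires the junction
#' `c = b+1`; the mismatch-mediated geometries require a single-base gap
#' `c = b+2` (geometry 1 additionally involves base `a-1`, geometry 2 base
#' `d+1`).  Wrong spacing is a precondition error; a non-canonical helix
#' end gives `+Inf`.
#'
#' @param kind `"flush"`, `"mismatch1"` or `"mismatch2"`.
#' @param a,b,c,d Positions of the two helix-end pairs.
#' @inheritParams hairpin_energy
#' @export
coaxial_energy <- function(kind = c("flush", "mismatch1", "mismatch2"),
                           seq, a, b, c, d, params) {
  kind <- match.arg(kind)
  seq <- as_rna_sequence(seq)
  codes <- seq$codes
  n <- length(codes)
  stopifnot(all(c(a, b, c, d) >= 1), all(c(a, b, c, d) <= n))
  if (kind == "flush") {
    if (c != b + 1L) stop("flush coaxial stack requires adjacent helix ends (c = b+1)",
                          call. = FALSE)
  } else {
    if (c != b + 2L) stop("mismatch-mediated coaxial stack requires a one-base gap (c = b+2)",
                          call. = FALSE)
  }
  p <- .pidx(codes, a, b)
  q <- .pidx(codes, c, d)
  if (p == 0L || q == 0L) return(Inf)
  switch(kind,
    flush     = params$coax_flush[p, q],
    mismatch1 = params$coax_mismatch1[p, q],
    mismatch2 = params$coax_mismatch2[p, q]
  )
}

#' Multibranch loop initiation
#'
#' \eqn{\Delta G = a + b\,n + c\,h} with `n` unpaired nucleotides and `h`
#' branching helices; `h` counts every helix in the loop including the
#' closing helix.
#'
#' @param n Unpaired nucleotide count (>= 0).
#' @param h Branching helix count (>= 0).
#' @inheritParams hairpin_energy
#' @export
multibranch_init <- function(n, h, params) {
  stopifnot(n >= 0, h >= 0)
  mb <- params$multibranch
  unname(mb["a"] + mb["b"] * n + mb["c"] * h)
}
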