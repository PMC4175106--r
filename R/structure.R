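#' Secondary structure objects
#'
#' A secondary structure is a partner assignment: an integer vector with
#' `partner[i] = j` when bases i and j pair and 0 when i is unpaired.  The
#' assignment must be an involution (`partner[partner[i]] == i`).
#' Structures produced by enumeration are pseudoknot-free; [probknot()]
#' output may contain crossing pairs.
#'
#' @param partner Integer vector of partners (0 = unpaired).
#' @return An object of class `secondary_structure`.
#' @examples
#' s <- secondary_structure(c(5, 0, 0, 0, 1))  # one pair (1,5)
#' structure_pairs(s)
#' @export
secondary_structure <- function(partner) {
  partner <- as.integer(partner)
  n <- length(partner)
  if (any(partner < 0 | partner > n)) {
    stop("partner indices must lie in 0..N", call. = FALSE)
  }
  paired <- which(partner > 0L)
  if (any(partner[paired] == paired)) {
    stop("a base cannot pair with itself", call. = FALSE)
  }
  if (any(partner[partner[paired]] != paired)) {
    stop("partner assignment is not an involution", call. = FALSE)
  }
  structure(partner, class = "secondary_structure")
}

#' @rdname secondary_structure
#' @param s A `secondary_structure`.
#' @return `structure_pairs()`: a 2-column matrix of pairs (i < j).
#' @export
structure_pairs <- function(s) {
  partner <- unclass(s)
  i <- which(partner > seq_along(partner))
  cbind(i = i, j = partner[i])
}

#' @export
print.secondary_structure <- function(x, ...) {
  np <- nrow(structure_pairs(x))
  cat(sprintf("secondary_structure: %d nt, %d pair(s)\n", length(x), np))
  invisible(x)
}

## TRUE iff the structure contains crossing pairs (a pseudoknot)
has_pseudoknot <- function(s) {
  pr <- structure_pairs(s)
  if (nrow(pr) < 2) return(FALSE)
  for (a in seq_len(nrow(pr) - 1)) {
    for (b in (a + 1):nrow(pr)) {
      i <- pr[a, 1]; j <- pr[a, 2]; k <- pr[b, 1]; l <- pr[b, 2]
      if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) return(TRUE)
    }
  }
  FALSE
}
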