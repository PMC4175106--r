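#' RNA sequence objects
#'
#' `rna_sequence()` validates and normalizes a base string.  Input is
#' upper-cased, whitespace is stripped and `T` is mapped to `U`; any
#' remaining character outside `A/C/G/U` is an error naming the offending
#' position (ambiguity codes are not accepted).  Positions are 1-based
#' throughout the package.
#'
#' @param x A single character string of bases, or an existing
#'   `rna_sequence`.
#' @param name Optional sequence description (kept for output headers).
#' @return An object of class `rna_sequence` with fields `bases` (the
#'   normalized string), `codes` (integer codes 1..4 for A,C,G,U) and
#'   `name`.
#' @examples
#' s <- rna_sequence("gattaca")   # T is mapped to U
#' as.character(s)
#' length(s)
#' @export
rna_sequence <- function(x, name = NULL) {
  if (inherits(x, "rna_sequence")) {
    if (!is.null(name)) x$name <- name
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  s <- toupper(gsub("[[:space:]]", "", x))
  s <- chartr("T", "U", s)
  if (nchar(s) < 1L) {
    stop("an RNA sequence must contain at least one base", call. = FALSE)
  }
  codes <- match(strsplit(s, "", fixed = TRUE)[[1L]], RNA_BASES)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1L]
    stop(sprintf(
      "illegal character '%s' at position %d (alphabet is A/C/G/U; T is accepted and mapped to U)",
      substr(s, bad, bad), bad
    ), call. = FALSE)
  }
  structure(
    list(bases = s, codes = as.integer(codes), name = name %||% ""),
    class = "rna_sequence"
  )
}

#' @export
length.rna_sequence <- function(x) nchar(x$bases)

#' @export
as.character.rna_sequence <- function(x, ...) x$bases

#' @export
print.rna_sequence <- function(x, ...) {
  n <- length(x)
  shown <- if (n > 60) paste0(substr(x$bases, 1, 57), "...") else x$bases
  cat(sprintf(
    "rna_sequence%s: %d nt\n  %s\n",
    if (nzchar(x$name)) paste0(" '", x$name, "'") else "", n, shown
  ))
  invisible(x)
}

#' Seeded random RNA sequences
#'
#' Draws an i.i.d. sequence over A/C/G/U from a given base composition
#' using a seeded generator, so the same `(length, composition, seed)`
#' always yields the same sequence.  Used throughout the studies in place
#' of database sequences.
#'
#' @param length Number of bases (>= 1).
#' @param composition Probability vector over A, C, G, U (normalized
#'   internally; must be non-negative with a positive sum).
#' @param seed Integer seed.
#' @return An [rna_sequence()].
#' @examples
#' random_rna_sequence(10, seed = 1)
#' @export
random_rna_sequence <- function(length,
                                composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                                seed = 1L) {
  stopifnot(length >= 1)
  composition <- as.numeric(composition)
  if (length(composition) != 4L || anyNA(composition) ||
      any(composition < 0) || sum(composition) <= 0) {
    stop("composition must be 4 non-negative probabilities over A,C,G,U with a positive sum",
         call. = FALSE)
  }
  composition <- composition / sum(composition)
  bases <- withr::with_seed(
    seed,
    sample(RNA_BASES, size = length, replace = TRUE, prob = composition)
  )
  rna_sequence(paste(bases, collapse = ""),
               name = sprintf("random_n%d_seed%d", as.integer(length), as.integer(seed)))
}

## Accept either a string or an rna_sequence in user-facing functions.
as_rna_sequence <- function(x) rna_sequence(x)
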