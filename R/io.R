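## Readers and writers.  All file formats use 1-based coordinates.

#' Read the first record of a FASTA file
#'
#' Parsing is delegated to Biostrings; the sequence is then normalized
#' and validated (`T` mapped to `U`, errors name the offending position).
#' Only the first record is folded; a multi-record file warns.
#'
#' @param path FASTA file path.
#' @return An [rna_sequence()] with the record description as `name`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file '%s' not found", path), call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("cannot parse FASTA file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE)
  )
  if (length(set) == 0L) stop(sprintf("FASTA file '%s' contains no records", path),
                              call. = FALSE)
  if (length(set) > 1L) {
    warning(sprintf("FASTA file '%s' has %d records; only the first is used",
                    path, length(set)), call. = FALSE)
  }
  rna_sequence(as.character(set[[1L]]), name = names(set)[1L])
}

#' Probability-table files
#'
#' Text dot-plot format: line 1 is the sequence length, line 2 the header
#' `i<TAB>j<TAB>-log10(Probability)`, then one row per pair `i < j` with
#' probability at or above the emission cutoff, values printed with 6
#' significant digits.  `read_probability_table()` reconstructs the
#' matrix (absent entries are 0), so write -> read round-trips emitted
#' entries to 6 significant digits.
#'
#' @param P Pair-probability matrix.
#' @param path File path.
#' @param cutoff Smallest probability emitted (default 1e-8).
#' @return `read_probability_table()`: a list with `N` and `prob`.
#' @export
write_probability_table <- function(P, path, cutoff = 1e-8) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  N <- nrow(P)
  lines <- c(as.character(N), "i\tj\t-log10(Probability)")
  idx <- which(upper.tri(P) & P >= cutoff, arr.ind = TRUE)
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    lines <- c(lines, sprintf("%d\t%d\t%.6g", idx[, 1L], idx[, 2L],
                              -log10(P[idx])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_probability_table
#' @export
read_probability_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed probability table: missing header", call. = FALSE)
  N <- suppressWarnings(as.integer(lines[1L]))
  if (is.na(N) || N < 1L) stop("malformed probability table: bad length line", call. = FALSE)
  if (!identical(lines[2L], "i\tj\t-log10(Probability)")) {
    stop("malformed probability table: unexpected header line", call. = FALSE)
  }
  P <- matrix(0, N, N)
  if (length(lines) > 2L) {
    body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
    for (row in body) {
      i <- as.integer(row[1L]); j <- as.integer(row[2L]); v <- as.numeric(row[3L])
      if (is.na(i) || is.na(j) || is.na(v) || i >= j || j > N) {
        stop("malformed probability table row", call. = FALSE)
      }
      P[i, j] <- 10^(-v)
    }
  }
  list(N = N, prob = P)
}

#' Write a CT (connectivity table) file
#'
#' Header `N title`, then one row per base with columns: index, base,
#' index-1, index+1, partner (0 if unpaired), index.
#'
#' @param structure A [secondary_structure()].
#' @param seq The sequence.
#' @param path File path.
#' @param title Optional title (defaults to the sequence name).
#' @export
write_ct <- function(structure, seq, path, title = NULL) {
  seq <- as_rna_sequence(seq)
  partner <- unclass(structure)
  N <- length(seq)
  stopifnot(length(partner) == N)
  title <- title %||% (if (nzchar(seq$name)) seq$name else "rnapf")
  bases <- strsplit(seq$bases, "", fixed = TRUE)[[1L]]
  lines <- c(
    sprintf("%d %s", N, title),
    sprintf("%d %s %d %d %d %d", seq_len(N), bases, seq_len(N) - 1L,
            seq_len(N) + 1L, partner, seq_len(N))
  )
  writeLines(lines, path)
  invisible(path)
}

## Assign pairs to bracket tiers so that pairs within one tier never
## cross; crossing pairs (pseudoknots) overflow into the next tier.
BRACKET_TIERS <- c("()", "[]", "{}", "<>")

#' Dot-bracket strings
#'
#' `dotbracket()` renders a structure as a bracket string, using
#' successive bracket tiers `()`, `[]`, `{}`, `<>` for crossing pairs
#' (ProbKnot output may be pseudoknotted).  `write_dotbracket()` writes
#' `>name`, sequence and brackets; `parse_dotbracket()` inverts the
#' rendering.
#'
#' @param structure A [secondary_structure()].
#' @return `dotbracket()`: a character string of the same length as the
#'   sequence.
#' @export
dotbracket <- function(structure) {
  partner <- unclass(structure)
  N <- length(partner)
  out <- rep(".", N)
  pr <- structure_pairs(structure)
  if (nrow(pr)) {
    tier <- integer(nrow(pr))
    ord <- order(pr[, 1L])
    pr <- pr[ord, , drop = FALSE]
    for (a in seq_len(nrow(pr))) {
      t <- 1L
      repeat {
        crossing <- FALSE
        for (b in seq_len(a - 1L)) {
          if (tier[b] != t) next
          i <- pr[b, 1L]; j <- pr[b, 2L]; k <- pr[a, 1L]; l <- pr[a, 2L]
          if ((i < k && k < j && j < l) || (k < i && i < l && l < j)) {
            crossing <- TRUE
            break
          }
        }
        if (!crossing) break
        t <- t + 1L
        if (t > length(BRACKET_TIERS)) {
          stop("structure needs more than 4 bracket tiers", call. = FALSE)
        }
      }
      tier[a] <- t
    }
    for (a in seq_len(nrow(pr))) {
      br <- BRACKET_TIERS[tier[a]]
      out[pr[a, 1L]] <- substr(br, 1L, 1L)
      out[pr[a, 2L]] <- substr(br, 2L, 2L)
    }
  }
  paste(out, collapse = "")
}

#' @rdname dotbracket
#' @inheritParams write_ct
#' @export
write_dotbracket <- function(structure, seq, path, title = NULL) {
  seq <- as_rna_sequence(seq)
  title <- title %||% (if (nzchar(seq$name)) seq$name else "rnapf")
  writeLines(c(paste0(">", title), seq$bases, dotbracket(structure)), path)
  invisible(path)
}

#' @rdname dotbracket
#' @param x A bracket string.
#' @export
parse_dotbracket <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  N <- length(chars)
  partner <- integer(N)
  stacks <- rep(list(integer(0)), length(BRACKET_TIERS))
  open <- substr(BRACKET_TIERS, 1L, 1L)
  close <- substr(BRACKET_TIERS, 2L, 2L)
  for (i in seq_len(N)) {
    ch <- chars[i]
    if (ch == ".") next
    t <- match(ch, open)
    if (!is.na(t)) {
      stacks[[t]] <- c(stacks[[t]], i)
      next
    }
    t <- match(ch, close)
    if (is.na(t)) stop(sprintf("bad dot-bracket character '%s' at position %d", ch, i),
                       call. = FALSE)
    k <- stacks[[t]]
    if (!length(k)) stop(sprintf("unbalanced bracket at position %d", i), call. = FALSE)
    j <- k[length(k)]
    stacks[[t]] <- k[-length(k)]
    partner[i] <- j
    partner[j] <- i
  }
  if (any(lengths(stacks) > 0L)) stop("unbalanced dot-bracket string", call. = FALSE)
  secondary_structure(partner)
}
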