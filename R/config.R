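#' Folding configuration
#'
#' Collects the model and implementation switches of the fill.  The
#' defaults are the full model: internal loops capped at 30 total unpaired
#' nucleotides, a minimum hairpin loop of 3, and dangling ends, terminal
#' mismatches and coaxial stacking all enabled.  Turning all three
#' adornment classes off gives "configuration-free" mode, where every
#' structure has a single energy given directly by its loop decomposition
#' (useful for non-circular oracle tests).
#'
#' @param internal_loop_cap Maximum total unpaired nucleotides in an
#'   internal/bulge loop (default 30); larger loops are forbidden.
#' @param min_hairpin Minimum unpaired bases in a hairpin loop (default 3).
#' @param dangles,terminal_mismatches,coaxial_stacking Logical toggles for
#'   the adornment classes in multibranch and exterior loops.
#' @param precision `"double"` (default) or `"single"`; in single
#'   precision all DP arrays and every log-sum are evaluated in 32-bit
#'   IEEE arithmetic (loop energies are evaluated in double and rounded on
#'   entry), mirroring a single-precision accelerator.
#' @param storage `"rolling"` (default; two diagonals each of W, W^L,
#'   W^MBL, five of W^MB) or `"full"` (debug mode that additionally keeps
#'   those arrays in full for inspection; results are bit-identical).
#' @return A `fold_config` object.
#' @examples
#' fold_config()                         # full model
#' fold_config(dangles = FALSE, terminal_mismatches = FALSE,
#'             coaxial_stacking = FALSE) # configuration-free mode
#' @export
fold_config <- function(internal_loop_cap = 30L,
                        min_hairpin = 3L,
                        dangles = TRUE,
                        terminal_mismatches = TRUE,
                        coaxial_stacking = TRUE,
                        precision = c("double", "single"),
                        storage = c("rolling", "full")) {
  precision <- match.arg(precision)
  storage <- match.arg(storage)
  stopifnot(internal_loop_cap >= 0, min_hairpin >= 0)
  structure(
    list(
      internal_loop_cap = as.integer(internal_loop_cap),
      min_hairpin = as.integer(min_hairpin),
      dangles = isTRUE(dangles),
      terminal_mismatches = isTRUE(terminal_mismatches),
      coaxial_stacking = isTRUE(coaxial_stacking),
      precision = precision,
      storage = storage
    ),
    class = "fold_config"
  )
}

#' @rdname fold_config
#' @param config A `fold_config`.
#' @export
configuration_free <- function(config) {
  !config$dangles && !config$terminal_mismatches && !config$coaxial_stacking
}

#' @export
print.fold_config <- function(x, ...) {
  cat(sprintf(
    "fold_config: cap=%d, min_hairpin=%d, dangles=%s, mismatches=%s, coax=%s, %s precision, %s storage\n",
    x$internal_loop_cap, x$min_hairpin, x$dangles, x$terminal_mismatches,
    x$coaxial_stacking, x$precision, x$storage
  ))
  invisible(x)
}
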