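## Shared alphabet and pair constants (loaded before the files that use
## them at top level).

#' @rdname rna_sequence
#' @export
RNA_BASES <- c("A", "C", "G", "U")

#' @rdname load_parameters
#' @export
CANONICAL_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Gas constant in kcal/(mol K)
#' @rdname load_parameters
#' @export
GAS_CONSTANT_KCAL <- 1.9872e-3

## 4x4 base-code -> ordered-pair index (0 = non-canonical)
PAIR_CODE <- matrix(0L, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
PAIR_CODE["A", "U"] <- 1L; PAIR_CODE["U", "A"] <- 2L
PAIR_CODE["G", "C"] <- 3L; PAIR_CODE["C", "G"] <- 4L
PAIR_CODE["G", "U"] <- 5L; PAIR_CODE["U", "G"] <- 6L
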