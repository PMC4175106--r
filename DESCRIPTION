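Package: rnapf
Title: RNA Secondary Structure Partition Functions by a Log-Space
    Nearest-Neighbor Dynamic Program
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes equilibrium partition functions and base-pair
    probabilities for single RNA sequences under a complete
    nearest-neighbor free-energy model with coaxial stacking, dangling
    ends and terminal mismatches.  The dynamic program works entirely in
    log space (free energies) using a numerically stable two-operand
    log-sum, and uses a memory-reduced array scheme that keeps four full
    N-by-N arrays plus one half-triangle instead of six full arrays.
    Includes exhaustive enumeration oracles for validation, a naive
    weight-space reference dynamic program, ProbKnot consensus
    structures, precision/perturbation/scaling studies, readers and
    writers for FASTA, CT, dot-bracket and probability-table formats,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    withr,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
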