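#' Numerically stable log-space sum of free energies
#'
#' `logsum(a, b)` returns \eqn{-\log(e^{-a} + e^{-b})} — the free energy
#' whose Boltzmann weight (in units with \eqn{RT = 1}) is the sum of the
#' two operand weights.  It is evaluated by the three-branch form
#' \deqn{f(a,b) = \min(a,b) - \mathrm{log1p}(e^{-|a-b|}),\qquad
#'       f(a,a) = a - \log 2,}
#' which needs at most one `exp` call and uses `log1p` so that the sum is
#' accurate even when the two weights differ by many orders of magnitude.
#' `+Inf` (weight 0) is the identity element; `logsum(Inf, Inf) = Inf`.
#'
#' `logsum_fold(values)` reduces a sequence left-to-right in ascending
#' index order (the fold order used, per accumulation site, throughout the
#' fill); an empty sequence gives `+Inf`.
#'
#' @param a,b Free energies in RT=1 units; `+-Inf` allowed.
#' @return The log-space sum; always `<= min(a, b)`.
#' @examples
#' logsum(1, 1)                 # 1 - log(2)
#' logsum(0, Inf)               # 0
#' logsum_fold(c(0, 0, 0, 0))   # -log(4)
#' @export
logsum <- function(a, b) {
  if (is.infinite(a) && a > 0) return(b)
  if (is.infinite(b) && b > 0) return(a)
  if (a < b) return(a - log1p(exp(a - b)))
  if (b < a) return(b - log1p(exp(b - a)))
  a - log(2)
}

#' @param values Numeric vector of free energies.
#' @rdname logsum
#' @export
logsum_fold <- function(values) {
  acc <- Inf
  for (v in values) acc <- logsum(acc, v)
  acc
}
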