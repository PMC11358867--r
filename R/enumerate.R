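# Exhaustive enumeration of canonical isomer barcodes.  This is the
# brute-force oracle for the closed-form count: every distinct permutation
# of the digit multiset is generated and only those equal to their own
# canonical form are kept.

#' Enumerate all unique isomer barcodes
#'
#' Generates every distinct assignment of the substituent digits to the ten
#' scaffold positions and keeps the canonical representative of each
#' rotation orbit exactly once.
#'
#' @inheritParams compute_S
#' @return Character vector of canonical barcodes, sorted lexicographically;
#'   its length equals [count_isomers()].
#' @export
#' @examples
#' enumerate_isomers(1)           # the 4 monosubstituted isomers
#' length(enumerate_isomers(2))   # 15
enumerate_isomers <- function(s) {
  scan <- .scan_barcodes(.digit_multiset(s), collect = TRUE)
  scan$barcodes
}

#' Brute-force classification counts for a substitution pattern
#'
#' One pass over all distinct digit assignments, returning the number of
#' assignments, of canonical barcodes (= unique isomers), of
#' rotation-invariant assignments (the brute-force value of S) and of
#' achiral isomers.  Used as the independent cross-check of [compute_S()]
#' and [count_isomers()].
#'
#' @inheritParams compute_S
#' @return Named list with `n_permutations`, `n_canonical`,
#'   `n_rho_invariant`, `n_achiral`.
#' @export
scan_isomers <- function(s) {
  out <- .scan_barcodes(.digit_multiset(s), collect = FALSE)
  lapply(out, as.numeric)
}

#' Chirality split of a substitution pattern
#'
#' @inheritParams compute_S
#' @return Named integer vector with `achiral`, `pairs` (enantiomeric
#'   pairs) and `total` isomer counts.
#' @export
chirality_split <- function(s) {
  scan <- scan_isomers(s)
  achiral <- as.integer(scan$n_achiral)
  total <- as.integer(scan$n_canonical)
  c(achiral = achiral, pairs = (total - achiral) %/% 2L, total = total)
}
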