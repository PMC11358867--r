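# Substituent sets: the multiset {N_a} of substituent types decorating the
# ten scaffold positions; hydrogen (type code 0) fills the remainder.

#' Define a substituent set
#'
#' A substituent set lists the non-hydrogen substituent types (as SMILES,
#' the first atom being the attachment atom) together with their
#' multiplicities; the remaining positions are implicitly hydrogen.
#' Entries whose SMILES canonicalise identically are merged with summed
#' counts, so the type identity is structural, not textual.
#'
#' @param smiles Character vector of substituent SMILES (e.g. `"C"` for
#'   methyl).
#' @param count Integer vector of multiplicities (recycled; default 1 each).
#' @param canonicalize Canonicalise the SMILES through Open Babel before
#'   merging duplicates (default: if Open Babel is available).
#' @return An object of class `bv_substituent_set` with fields `smiles`
#'   (canonical), `input_smiles`, `count` and `code` (type codes 1..k in
#'   input order).
#' @export
#' @examples
#' substituent_set("C", 2)                    # dimethyl
#' substituent_set(c("C", "O", "N"))          # three distinct types
substituent_set <- function(smiles = character(), count = 1L,
                            canonicalize = ob_available()) {
  smiles <- as.character(smiles)
  count <- as.integer(rep_len(count, length(smiles)))
  if (any(is.na(count)) || any(count < 1L))
    stop("substituent counts must be positive integers", call. = FALSE)
  if (any(!nzchar(smiles)) || anyNA(smiles))
    stop("substituent SMILES must be non-empty strings", call. = FALSE)
  key <- smiles
  if (length(smiles) && canonicalize) {
    key <- vapply(smiles, ob_canonical_smiles, character(1), USE.NAMES = FALSE)
    if (any(key %in% c("[H]", "[HH]")))
      stop("hydrogen is implicit and cannot be listed as a substituent",
           call. = FALSE)
  }
  # merge structurally identical entries, keeping first-seen order
  ord <- !duplicated(key)
  merged_key <- key[ord]
  merged_count <- vapply(merged_key, function(k) sum(count[key == k]),
                         integer(1), USE.NAMES = FALSE)
  if (sum(merged_count) > 10L)
    stop("substituent counts sum to ", sum(merged_count),
         "; at most 10 scaffold positions exist", call. = FALSE)
  structure(
    list(smiles = merged_key,
         input_smiles = smiles[ord],
         count = merged_count,
         code = seq_along(merged_key)),
    class = "bv_substituent_set")
}

#' @export
print.bv_substituent_set <- function(x, ...) {
  k <- length(x$smiles)
  cat("Bullvalene substituent set: ", k, " non-hydrogen type",
      if (k != 1) "s", ", ", n_hydrogen(x), " hydrogens\n", sep = "")
  if (k)
    cat(sprintf("  [%s] %s x %d\n", BV_ALPHABET[x$code + 1L], x$smiles,
                x$count), sep = "")
  invisible(x)
}

#' Number of implicit hydrogens of a substituent set
#' @param s A `bv_substituent_set`.
#' @return Integer in 0..10.
#' @export
n_hydrogen <- function(s) {
  stopifnot(inherits(s, "bv_substituent_set"))
  10L - sum(s$count)
}

# Full per-type counts (hydrogen first, code 0) from a substituent set or a
# bare vector of non-hydrogen counts.  Returns a named integer vector whose
# names are the digit codes.
.type_counts <- function(x) {
  if (inherits(x, "bv_substituent_set")) {
    counts <- x$count
  } else if (is.numeric(x)) {
    counts <- as.integer(x)
    counts <- counts[counts > 0L]
    if (sum(counts) > 10L)
      stop("substituent counts sum to more than 10", call. = FALSE)
  } else {
    stop("expected a bv_substituent_set or a vector of substituent counts",
         call. = FALSE)
  }
  full <- c(10L - sum(counts), counts)
  names(full) <- BV_ALPHABET[seq_along(full)]
  full
}

# The sorted digit multiset (length 10) for enumeration.
.digit_multiset <- function(x) {
  full <- .type_counts(x)
  rep(seq_along(full) - 1L, full)
}

# Parse CLI-style "SMILES:count" pairs into a substituent set.
parse_substituent_spec <- function(spec, canonicalize = ob_available()) {
  if (!length(spec)) return(substituent_set())
  parts <- regmatches(spec, regexec("^(.*?)(?::([0-9]+))?$", spec))
  smiles <- vapply(parts, `[`, character(1), 2L)
  count <- vapply(parts, `[`, character(1), 3L)
  count <- ifelse(nzchar(count), count, "1")
  substituent_set(smiles, as.integer(count), canonicalize = canonicalize)
}
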