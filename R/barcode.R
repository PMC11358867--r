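# Isomer barcodes
#
# A barcode is a string of 10 digit characters, one per scaffold carbon, in
# the fixed position order
#   [alpha, beta1, gamma1, delta1, beta2, gamma2, delta2, beta3, gamma3, delta3]
# where digit 0 is hydrogen and non-hydrogen substituent types are numbered
# 1..k (serialised through the alphabet 0-9a-z so that up to ten distinct
# non-hydrogen types still fit one character per position).

BV_NPOS <- 10L

# (rho b)[p] = b[BV_RHO[p]]; cycles arms 1 -> 2 -> 3, fixes alpha.
BV_RHO <- c(1L, 8L, 9L, 10L, 2L, 3L, 4L, 5L, 6L, 7L)
# mirror: fixes alpha and arm 1, swaps arms 2 and 3 site-wise.
BV_SIGMA <- c(1L, 2L, 3L, 4L, 8L, 9L, 10L, 5L, 6L, 7L)

BV_ALPHABET <- c(as.character(0:9), letters)

# Human-readable locants for the ten positions (primes distinguish arms).
BV_LOCANTS <- c("alpha",
                "beta", "gamma", "delta",
                "beta'", "gamma'", "delta'",
                "beta''", "gamma''", "delta''")

#' Positional locants of the bullvalene scaffold
#'
#' Returns the Greek-letter locants in barcode position order: the apical
#' sp3 carbon `alpha`, then `beta`, `gamma`, `delta` for each of the three
#' arms (primes distinguish arms).
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' bv_locants()
bv_locants <- function() BV_LOCANTS

# ---- internal representation ------------------------------------------------

# digits as integer vector <-> serialised 10-character string
.barcode_to_int <- function(b) {
  if (is.numeric(b)) {
    b <- as.integer(b)
    if (length(b) != BV_NPOS || anyNA(b) || any(b < 0L) || any(b > 35L))
      stop("a barcode must have 10 digit codes in 0..35", call. = FALSE)
    return(b)
  }
  if (!is.character(b) || length(b) != 1L || nchar(b) != BV_NPOS)
    stop("a barcode must be a 10-character string (or 10 integer codes)",
         call. = FALSE)
  codes <- match(strsplit(b, "", fixed = TRUE)[[1]], BV_ALPHABET) - 1L
  if (anyNA(codes))
    stop("invalid barcode character in '", b, "' (allowed: 0-9, a-z)",
         call. = FALSE)
  codes
}

.barcode_to_string <- function(codes) {
  paste(BV_ALPHABET[codes + 1L], collapse = "")
}

# apply a position permutation: (perm b)[p] = b[perm[p]]
.perm_apply <- function(codes, perm) codes[perm]

# compose permutation arrays so that applying `ab` equals applying `a` then `b`
.perm_compose <- function(a, b) a[b]

# ---- exported operations ----------------------------------------------------

#' Canonical form of an isomer barcode
#'
#' Two barcodes related by the threefold rotation of the bullvalene scaffold
#' describe the same isomer.  The canonical representative of a rotation
#' orbit is the lexicographically greatest of the three arm rotations, which
#' places non-hydrogen substituents at the earliest possible positions
#' (arm 1).  Reflections are deliberately not quotiented out, so enantiomers
#' remain distinct barcodes.
#'
#' @param barcode A 10-character barcode string (or 10 integer digit codes).
#' @return The canonical barcode string.  Idempotent.
#' @seealso [bv_orbit()], [classify_chirality()]
#' @export
#' @examples
#' canonical_form("0000100000")  # substituent at beta' moves to beta
canonical_form <- function(barcode) {
  codes <- .barcode_to_int(barcode)
  r1 <- .perm_apply(codes, BV_RHO)
  r2 <- .perm_apply(r1, BV_RHO)
  strs <- c(.barcode_to_string(codes), .barcode_to_string(r1),
            .barcode_to_string(r2))
  max(strs)
}

#' Rotation orbit of a barcode
#'
#' @param barcode A barcode string or digit codes.
#' @return Character vector of the distinct arm rotations (length 1 or 3).
#' @export
bv_orbit <- function(barcode) {
  codes <- .barcode_to_int(barcode)
  r1 <- .perm_apply(codes, BV_RHO)
  r2 <- .perm_apply(r1, BV_RHO)
  unique(c(.barcode_to_string(codes), .barcode_to_string(r1),
           .barcode_to_string(r2)))
}

#' Mirror image of a barcode
#'
#' Applies the scaffold reflection (alpha and arm 1 fixed, arms 2 and 3
#' swapped site-wise).  The result is generally not canonical; see
#' [classify_chirality()] for the canonical enantiomer partner.
#'
#' @param barcode A barcode string or digit codes.
#' @return The reflected barcode string.
#' @export
reflect_barcode <- function(barcode) {
  .barcode_to_string(.perm_apply(.barcode_to_int(barcode), BV_SIGMA))
}

#' Chirality classification of an isomer barcode
#'
#' An isomer is achiral when its mirror image is rotation-equivalent to
#' itself; otherwise it is one member of an enantiomeric pair and the partner
#' is the canonical form of the mirror image.
#'
#' @param barcode A barcode (canonicalised internally).
#' @return A list with elements `barcode` (canonical form), `chirality`
#'   (`"achiral"` or `"chiral"`) and `partner` (canonical enantiomer barcode
#'   for chiral isomers, `NA` otherwise).
#' @export
#' @examples
#' classify_chirality("1100000000")
classify_chirality <- function(barcode) {
  b <- canonical_form(barcode)
  partner <- canonical_form(reflect_barcode(b))
  if (identical(partner, b)) {
    list(barcode = b, chirality = "achiral", partner = NA_character_)
  } else {
    list(barcode = b, chirality = "chiral", partner = partner)
  }
}

#' Build a barcode from positional locants
#'
#' Convenience constructor: place substituent type codes at named positions.
#' Position names are the locants of [bv_locants()] (`"beta'"` is the beta
#' position of arm 2, etc.).
#'
#' @param locants Character vector of locants to substitute.
#' @param codes Integer type codes for each locant (default all 1, i.e. a
#'   single substituent type).
#' @param canonical Canonicalise the result (default `TRUE`).
#' @return A barcode string.
#' @export
#' @examples
#' barcode_from_locants(c("beta", "beta'"))   # beta,beta'-disubstituted
barcode_from_locants <- function(locants, codes = 1L, canonical = TRUE) {
  pos <- match(locants, BV_LOCANTS)
  if (anyNA(pos))
    stop("unknown locant(s): ",
         paste(locants[is.na(pos)], collapse = ", "),
         " (see bv_locants())", call. = FALSE)
  if (anyDuplicated(pos))
    stop("duplicated locants", call. = FALSE)
  b <- integer(BV_NPOS)
  b[pos] <- as.integer(rep_len(codes, length(pos)))
  s <- .barcode_to_string(b)
  if (canonical) canonical_form(s) else s
}

#' Locant description of a barcode
#'
#' @param barcode A barcode string.
#' @return A character scalar such as `"beta,gamma'"` listing the substituted
#'   locants (with type codes appended when more than one type is present),
#'   or `"parent"` for the unsubstituted scaffold.
#' @export
describe_barcode <- function(barcode) {
  codes <- .barcode_to_int(barcode)
  sub <- which(codes > 0L)
  if (!length(sub)) return("parent")
  lab <- BV_LOCANTS[sub]
  if (length(unique(codes[sub])) > 1L)
    lab <- paste0(lab, "(", BV_ALPHABET[codes[sub] + 1L], ")")
  paste(lab, collapse = ",")
}
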