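# Shape descriptors: principal moments of inertia (normalised PMI ratios)
# and exit-vector geometry for substituent pairs.

#' Principal moments of inertia and normalised ratios
#'
#' Computes the centre-of-mass inertia tensor over all atoms with standard
#' atomic masses, its eigenvalues I1 <= I2 <= I3 (amu A^2) and the
#' normalised ratios NPR1 = I1/I3 and NPR2 = I2/I3.  On the standard
#' triangular PMI plot the vertices are rod (0, 1), disc (0.5, 0.5) and
#' sphere (1, 1); the sum NPR1 + NPR2 lies in [1, 2] by the
#' perpendicular-axis bound.
#'
#' @param x A [bv_structure], or a list with `coords` (n x 3 matrix) and
#'   either `masses` or `elements`.
#' @return A list of class `bv_pmi` with `I1`, `I2`, `I3`, `NPR1`, `NPR2`,
#'   `SNPR` and a logical `collinear` flag (for degenerate rod-like input
#'   NPR1 = 0, NPR2 = 1 is returned and flagged).
#' @export
#' @examples
#' rod <- list(coords = rbind(c(0, 0, -1), c(0, 0, 1)), masses = c(1, 1))
#' pmi(rod)$NPR1
pmi <- function(x) {
  coords <- as.matrix(x$coords)
  masses <- if (!is.null(x$masses)) x$masses else atomic_masses(x$elements)
  stopifnot(nrow(coords) == length(masses), ncol(coords) == 3)
  if (nrow(coords) < 2L)
    stop("at least two atoms are needed for an inertia tensor", call. = FALSE)
  com <- colSums(coords * masses) / sum(masses)
  X <- sweep(coords, 2, com)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(X^2)
  for (i in 1:3) {
    I[i, i] <- sum(masses * (r2 - X[, i]^2))
    for (j in 1:3) if (j != i) I[i, j] <- -sum(masses * X[, i] * X[, j])
  }
  ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  ev[ev < 0 & ev > -1e-9] <- 0
  collinear <- ev[3] <= 0 || ev[1] / ev[3] < 1e-12
  out <- list(I1 = ev[1], I2 = ev[2], I3 = ev[3],
              NPR1 = if (ev[3] > 0) ev[1] / ev[3] else 0,
              NPR2 = if (ev[3] > 0) ev[2] / ev[3] else 1,
              collinear = collinear)
  out$SNPR <- out$NPR1 + out$NPR2
  class(out) <- "bv_pmi"
  out
}

#' @export
print.bv_pmi <- function(x, ...) {
  cat(sprintf("PMI: I1 = %.2f, I2 = %.2f, I3 = %.2f amu A^2\n",
              x$I1, x$I2, x$I3))
  cat(sprintf("     NPR1 = %.3f, NPR2 = %.3f, sum = %.3f%s\n",
              x$NPR1, x$NPR2, x$SNPR,
              if (x$collinear) " (collinear)" else ""))
  invisible(x)
}

# signed dihedral angle p1-p2-p3-p4 (degrees, right-handed, -180..180)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

.vec_angle <- function(a, b) {
  cosv <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

# plane angle between an exit vector and the internuclear axis.  The
# default convention directs the axis away from the partner carbon
# (C_j -> C_i extended); the complement convention is the supplement.
.ev_phi <- function(v, axis_away, convention = c("away", "complement")) {
  convention <- match.arg(convention)
  a <- .vec_angle(v, axis_away)
  if (convention == "complement") 180 - a else a
}

#' Exit-vector geometry of a substituent pair
#'
#' For two substituted positions the exit vectors run from the scaffold
#' carbons C1, C2 to the substituent attachment atoms X1, X2.  The
#' descriptors are the scaffold carbon distance `r = |C1 C2|`, the signed
#' dihedral `theta` = X1-C1-C2-X2 (right-handed convention, so mirror-image
#' coordinates negate it) and the plane angles `phi1`, `phi2` between each
#' exit vector and the internuclear axis directed away from the partner
#' carbon.
#'
#' @param st A [bv_structure] with substituents at `p` and `q`.
#' @param p,q Barcode positions (1..10) of the two substituents; the sign
#'   of theta refers to the (lower, higher) position ordering.
#' @param phi_convention `"away"` (default) or `"complement"`.
#' @return A data frame row of class `bv_ev`: `barcode`, `pos1`, `pos2`,
#'   `locants`, `r`, `theta`, `phi1`, `phi2`.
#' @export
exit_vectors <- function(st, p, q, phi_convention = "away") {
  p <- as.integer(p); q <- as.integer(q)
  for (pos in c(p, q))
    if (!as.character(pos) %in% names(st$attachment_map))
      stop("position ", pos, " (", BV_LOCANTS[pos],
           ") carries no substituent in this structure", call. = FALSE)
  if (p > q) { tmp <- p; p <- q; q <- tmp }
  C1 <- st$coords[st$position_map[p], ]
  C2 <- st$coords[st$position_map[q], ]
  X1 <- st$coords[st$attachment_map[[as.character(p)]], ]
  X2 <- st$coords[st$attachment_map[[as.character(q)]], ]
  r <- sqrt(sum((C1 - C2)^2))
  theta <- .dihedral(X1, C1, C2, X2)
  out <- data.frame(
    barcode = st$barcode, pos1 = p, pos2 = q,
    locants = paste(BV_LOCANTS[c(p, q)], collapse = ","),
    r = r, theta = theta,
    phi1 = .ev_phi(X1 - C1, C1 - C2, phi_convention),
    phi2 = .ev_phi(X2 - C2, C2 - C1, phi_convention),
    stringsAsFactors = FALSE)
  class(out) <- c("bv_ev", class(out))
  out
}

#' Exit vectors for every substituent pair of a structure
#'
#' @param st A [bv_structure] with at least two substituents.
#' @inheritParams exit_vectors
#' @return Data frame with one row per unordered pair (k substituents give
#'   k(k-1)/2 rows).
#' @export
all_pairs_ev <- function(st, phi_convention = "away") {
  pos <- sort(as.integer(names(st$attachment_map)))
  if (length(pos) < 2L)
    stop("at least two substituents are needed for exit-vector analysis",
         call. = FALSE)
  pairs <- combn(pos, 2L)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(i)
    exit_vectors(st, pairs[1L, i], pairs[2L, i],
                 phi_convention = phi_convention)))
}

# ---- descriptor tables ------------------------------------------------------

# accept a list of bv_conformers (taking the best structure each) or of
# bv_structure
.best_structures <- function(x) {
  if (inherits(x, "bv_structure")) return(list(x))
  if (inherits(x, "bv_conformers")) return(list(best_structure(x)))
  x <- Filter(function(e) !inherits(e, "bv_build_error"), x)
  lapply(x, function(e) if (inherits(e, "bv_conformers")) best_structure(e)
         else e)
}

#' PMI descriptor table over a set of isomers
#'
#' @param structures A list of [bv_structure]s or of conformer batches from
#'   [build_isomers()] (the lowest-energy structure of each is used).
#' @return Data frame: one row per isomer with `barcode`, `locants`,
#'   `I1..I3`, `NPR1`, `NPR2`, `SNPR` and `energy` (kJ/mol where known).
#' @export
pmi_table <- function(structures) {
  sts <- .best_structures(structures)
  do.call(rbind, lapply(sts, function(st) {
    p <- pmi(st)
    data.frame(barcode = st$barcode, locants = describe_barcode(st$barcode),
               I1 = p$I1, I2 = p$I2, I3 = p$I3,
               NPR1 = p$NPR1, NPR2 = p$NPR2, SNPR = p$SNPR,
               energy = st$energy, stringsAsFactors = FALSE)
  }))
}

#' Exit-vector descriptor table over a set of isomers
#'
#' @inheritParams pmi_table
#' @inheritParams exit_vectors
#' @return Data frame: one row per (isomer, substituent pair).
#' @export
ev_table <- function(structures, phi_convention = "away") {
  sts <- .best_structures(structures)
  do.call(rbind, lapply(sts, all_pairs_ev, phi_convention = phi_convention))
}

#' Write a descriptor table as CSV
#'
#' @param table A data frame from [pmi_table()], [ev_table()] or
#'   [weighted_descriptor_table()].
#' @param file Output path.
#' @param rounded Round to reporting precision (0.1 A for distances, 1
#'   degree for angles, 3 decimals for NPR ratios).
#' @return `file`, invisibly.
#' @export
write_descriptor_csv <- function(table, file, rounded = FALSE) {
  if (rounded) {
    for (col in intersect(c("r"), names(table)))
      table[[col]] <- round(table[[col]], 1L)
    for (col in intersect(c("theta", "phi1", "phi2"), names(table)))
      table[[col]] <- round(table[[col]])
    for (col in intersect(c("NPR1", "NPR2", "SNPR"), names(table)))
      table[[col]] <- round(table[[col]], 3L)
  }
  write.csv(table, file, row.names = FALSE)
  invisible(file)
}
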