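# The parent bullvalene scaffold template.
#
# Atom order: carbons 1..10 in barcode position order (alpha, then beta,
# gamma, delta of arms 1..3), hydrogens 11..20 with H(10+p) bonded to
# carbon p.  The template is embedded once from the parent SMILES with the
# deterministic Open Babel builder, force-field relaxed, and then averaged
# over the six C3v symmetry operations so that symmetry-related positions
# are exactly equivalent (grafts at mirror-related positions then start
# from exactly mirror-image geometries).

BV_PARENT_SMILES <- "C(C=CC12)(C=CC13)C=CC23"

# scaffold bonds (i, j, order): alpha-beta, beta=gamma, gamma-delta and the
# cyclopropane delta-delta ring
BV_SCAFFOLD_BONDS <- local({
  arm <- function(b) rbind(c(1L, b, 1L), c(b, b + 1L, 2L),
                           c(b + 1L, b + 2L, 1L))
  rbind(arm(2L), arm(5L), arm(8L),
        c(4L, 7L, 1L), c(7L, 10L, 1L), c(4L, 10L, 1L))
})

.bv_template_bonds <- function() {
  rbind(BV_SCAFFOLD_BONDS, cbind(1:10, 11:20, 1L))
}

# atom-level permutations of the 20 template atoms for the symmetry ops
.template_atom_perm <- function(pos_perm) c(pos_perm, 10L + pos_perm)

# Average coordinates over the C3v group.  Each permuted copy is aligned
# onto the running structure by least squares (allowing improper rotations
# for the mirror operations) and the aligned copies are averaged; iterated
# to convergence.
.symmetrize_c3v <- function(coords) {
  pos_perms <- list(1:10, BV_RHO, BV_RHO[BV_RHO],
                    BV_SIGMA, BV_SIGMA[BV_RHO], BV_RHO[BV_SIGMA])
  coords <- sweep(coords, 2, colMeans(coords))
  for (iter in 1:25) {
    acc <- 0
    for (pp in pos_perms) {
      ap <- .template_atom_perm(pp)
      s <- svd(crossprod(coords[ap, , drop = FALSE], coords))
      rot <- s$u %*% t(s$v)  # best orthogonal map, improper allowed
      acc <- acc + coords[ap, , drop = FALSE] %*% rot
    }
    new <- sweep(acc / length(pos_perms), 2, colMeans(acc / length(pos_perms)))
    delta <- max(abs(new - coords))
    coords <- new
    if (delta < 1e-12) break
  }
  coords
}

.template_sanity <- function(coords) {
  d <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  dd <- c(d(4, 7), d(7, 10), d(4, 10))   # cyclopropane
  bg <- c(d(2, 3), d(5, 6), d(8, 9))     # olefinic
  all(abs(dd - 1.5) < 0.1) && all(abs(bg - 1.34) < 0.1)
}

#' The parent bullvalene 3D template
#'
#' Embeds and relaxes the parent C10H10 cage, symmetrises it to exact C3v
#' geometry and returns it as a [bv_structure] whose `position_map` sends
#' barcode position p to carbon p (hydrogen 10+p).  The result is cached
#' for the session.  If embedding is unavailable or produces a distorted
#' cage, the bundled reference coordinates are used instead.
#'
#' @param rebuild Force a rebuild instead of using the session cache.
#' @return A `bv_structure` for the parent scaffold (barcode
#'   `"0000000000"`).
#' @export
bv_core_template <- function(rebuild = FALSE) {
  if (!rebuild && !is.null(.bv_env$template)) return(.bv_env$template)
  coords <- NULL
  if (ob_available()) {
    mol <- tryCatch(.ob_embed_smiles(BV_PARENT_SMILES),
                    error = function(e) NULL)
    if (!is.null(mol) && identical(mol$elements, c(rep("C", 10), rep("H", 10)))) {
      cand <- .symmetrize_c3v(mol$coords)
      if (.template_sanity(cand)) coords <- cand
    }
  }
  if (is.null(coords)) {
    xyz <- read_xyz(system.file("extdata", "bullvalene_core.xyz",
                                package = "bvstereo", mustWork = TRUE))
    coords <- .symmetrize_c3v(xyz$coords)
  }
  st <- new_bv_structure(
    elements = c(rep("C", 10), rep("H", 10)),
    coords = coords,
    bonds = .bv_template_bonds(),
    barcode = strrep("0", 10),
    position_map = 1:10,
    attachment_map = integer(0),
    provenance = "force-field")
  .bv_env$template <- st
  st
}
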