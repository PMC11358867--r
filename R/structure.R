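# 3D structures of individual isomers: substituent grafting onto the
# scaffold template, conformer generation and force-field refinement.

#' Construct a bv_structure
#'
#' The container for one 3D structure: element symbols, Cartesian
#' coordinates (Angstrom), the bond list of the underlying graph, the
#' isomer barcode, a `position_map` from barcode positions to scaffold
#' carbon atom indices and an `attachment_map` from substituted positions
#' to the first atom of the grafted substituent.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix (n x 3), Angstrom.
#' @param bonds Integer matrix (m x 3): atom i, atom j, bond order.
#' @param barcode Canonical isomer barcode string.
#' @param position_map Integer vector of length 10.
#' @param attachment_map Named integer vector (names = barcode positions of
#'   the substituted sites).
#' @param energy Optional energy value.
#' @param energy_unit Unit tag for `energy` (default `"kJ/mol"`).
#' @param provenance `"force-field"` or `"external-QC"`.
#' @return An object of class `bv_structure`.
#' @export
new_bv_structure <- function(elements, coords, bonds, barcode,
                             position_map, attachment_map = integer(0),
                             energy = NA_real_, energy_unit = "kJ/mol",
                             provenance = "force-field") {
  coords <- as.matrix(coords)
  stopifnot(length(elements) == nrow(coords), ncol(coords) == 3,
            length(position_map) == 10L)
  structure(
    list(elements = elements, coords = coords, bonds = bonds,
         barcode = barcode, position_map = as.integer(position_map),
         attachment_map = attachment_map, energy = energy,
         energy_unit = energy_unit, provenance = provenance),
    class = "bv_structure")
}

#' @export
print.bv_structure <- function(x, ...) {
  cat("Bullvalene isomer structure\n")
  cat("  barcode:   ", x$barcode, " (", describe_barcode(x$barcode), ")\n",
      sep = "")
  cat("  formula:   ", molecular_formula(x), "\n", sep = "")
  if (!is.na(x$energy))
    cat("  energy:    ", format(x$energy), " ", x$energy_unit, "\n", sep = "")
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' Molecular formula of a structure
#'
#' @param st A `bv_structure`.
#' @return Hill-order formula string (C first, H second, rest alphabetical).
#' @export
molecular_formula <- function(st) {
  tab <- table(st$elements)
  ord <- c(intersect(c("C", "H"), names(tab)),
           sort(setdiff(names(tab), c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (tab[[e]] > 1L) tab[[e]] else ""), character(1)),
    collapse = "")
}

#' Atom masses of a structure
#' @param st A `bv_structure`.
#' @return Numeric vector of standard atomic masses (Da).
#' @export
structure_masses <- function(st) atomic_masses(st$elements)

# ---- substituent fragments --------------------------------------------------

# Embed a substituent SMILES once and cache it.  The attachment atom is the
# first atom of the SMILES; one of its hydrogens is sacrificed for the bond
# to the scaffold, and its direction defines the fragment's bond axis.
#
# The raw Open Babel embedding carries a random rigid orientation, so the
# fragment is tightly minimised and then brought into a canonical frame
# (attachment atom at the origin, bond axis along -z, roll fixed by the
# first remaining neighbour, atoms re-sorted by position); for rigid
# substituents this makes the geometry reproducible across sessions.
.substituent_fragment <- function(smiles) {
  key <- paste0("frag:", smiles)
  if (!is.null(.bv_env[[key]])) return(.bv_env[[key]])
  mol <- .ob_embed_smiles(smiles)
  h <- .bonded_atoms(mol$bonds, 1L)
  h <- h[mol$elements[h] == "H"]
  if (!length(h))
    stop("substituent '", smiles, "' has no free valence (no hydrogen) on ",
         "its attachment atom; cannot graft", call. = FALSE)
  if (length(mol$elements) > 2L) {
    # two rounds: minimise, snap to the canonical frame on a coarse grid,
    # and re-minimise from that start, so the random orientation and most
    # of the path noise of the embedding drop out
    mol <- .ob_minimize(mol, "MMFF94", steps = 50000, crit = 1e-10)
    snap <- .canonical_fragment_frame(mol, attach = 1L,
                                      h_removed = h[[1L]], digits = 2L)
    h <- snap$h_removed
    mol <- .ob_minimize(snap, "MMFF94", steps = 50000, crit = 1e-10)
  }
  frag <- .canonical_fragment_frame(mol, attach = 1L, h_removed = h[[1L]])
  .bv_env[[key]] <- frag
  frag
}

.bonded_atoms <- function(bonds, i) {
  c(bonds[bonds[, 1L] == i, 2L], bonds[bonds[, 2L] == i, 1L])
}

.canonical_fragment_frame <- function(mol, attach, h_removed, digits = 4L) {
  co <- sweep(mol$coords, 2, mol$coords[attach, ])
  axis <- co[h_removed, ]
  co <- co %*% t(.rotation_between(axis / sqrt(sum(axis^2)), c(0, 0, -1)))
  # fix the roll using the first neighbour of the attachment atom that is
  # not the sacrificed hydrogen (heavy atoms first)
  nb <- setdiff(.bonded_atoms(mol$bonds, attach), h_removed)
  nb <- nb[order(mol$elements[nb] == "H", nb)]
  if (length(nb)) {
    v <- co[nb[[1L]], ]
    if (sqrt(v[1]^2 + v[2]^2) > 1e-6) {
      phi <- atan2(v[2], v[1])
      co <- co %*% t(.rotation_about_axis(c(0, 0, 1), -phi))
    }
  }
  co <- round(co, digits)
  # canonical atom order: attachment atom first, the rest sorted by
  # element and rounded position (stable for symmetry-equivalent atoms)
  rest <- setdiff(seq_along(mol$elements), attach)
  ord <- c(attach,
           rest[order(mol$elements[rest],
                      round(co[rest, 3L], 3L), round(co[rest, 1L], 3L),
                      round(co[rest, 2L], 3L))])
  inv <- match(seq_along(ord), ord)
  bonds <- mol$bonds
  bonds[, 1L] <- inv[bonds[, 1L]]
  bonds[, 2L] <- inv[bonds[, 2L]]
  list(elements = mol$elements[ord], coords = co[ord, , drop = FALSE],
       bonds = bonds, attach = 1L, h_removed = inv[h_removed])
}

# rotation matrix taking unit vector a to unit vector b
.rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {  # antiparallel: rotate pi about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a
    v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

.rotation_about_axis <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Graft substituents onto the template at the non-hydrogen positions of a
# barcode.  `rolls` gives the torsion (radians) of each fragment about its
# new bond axis, in barcode-position order of the substituted sites.
.graft_barcode <- function(b_codes, sset, rolls = NULL) {
  tmpl <- bv_core_template()
  sub_pos <- which(b_codes > 0L)
  if (is.null(rolls)) rolls <- numeric(length(sub_pos))
  keep <- setdiff(seq_len(20L), 10L + sub_pos)  # drop substituted H atoms
  map <- match(seq_len(20L), keep)
  elements <- tmpl$elements[keep]
  coords <- tmpl$coords[keep, , drop = FALSE]
  bonds <- tmpl$bonds
  bonds <- bonds[!(bonds[, 1L] %in% (10L + sub_pos) |
                   bonds[, 2L] %in% (10L + sub_pos)), , drop = FALSE]
  bonds[, 1L] <- map[bonds[, 1L]]
  bonds[, 2L] <- map[bonds[, 2L]]
  attachment <- integer(0)
  for (i in seq_along(sub_pos)) {
    p <- sub_pos[i]
    frag <- .substituent_fragment(sset$smiles[b_codes[p]])
    exit <- tmpl$coords[10L + p, ] - tmpl$coords[p, ]
    exit <- exit / sqrt(sum(exit^2))
    blen <- .covalent_radius("C") + .covalent_radius(frag$elements[frag$attach])
    anchor <- tmpl$coords[p, ] + blen * exit
    # orient: the fragment's (attach -> removed H) direction must point back
    # towards the scaffold carbon
    fdir <- frag$coords[frag$h_removed, ] - frag$coords[frag$attach, ]
    fdir <- fdir / sqrt(sum(fdir^2))
    rot <- .rotation_between(fdir, -exit)
    fco <- sweep(frag$coords, 2, frag$coords[frag$attach, ])
    fco <- fco %*% t(rot)
    if (rolls[i] != 0)
      fco <- fco %*% t(.rotation_about_axis(exit, rolls[i]))
    fco <- sweep(fco, 2, -anchor)
    fkeep <- setdiff(seq_along(frag$elements), frag$h_removed)
    fmap <- match(seq_along(frag$elements), fkeep)
    offset <- length(elements)
    elements <- c(elements, frag$elements[fkeep])
    coords <- rbind(coords, fco[fkeep, , drop = FALSE])
    fb <- frag$bonds[!(frag$bonds[, 1L] == frag$h_removed |
                       frag$bonds[, 2L] == frag$h_removed), , drop = FALSE]
    if (nrow(fb)) {
      fb[, 1L] <- fmap[fb[, 1L]] + offset
      fb[, 2L] <- fmap[fb[, 2L]] + offset
    }
    bonds <- rbind(bonds, fb,
                   c(map[p], fmap[frag$attach] + offset, 1L))
    attachment[as.character(p)] <- fmap[frag$attach] + offset
  }
  list(elements = elements, coords = coords, bonds = bonds,
       attachment = attachment)
}

# ---- isomer building --------------------------------------------------------

.validate_barcode_set <- function(b_codes, sset) {
  want <- sort(.digit_multiset(sset))
  have <- sort(b_codes)
  if (!identical(as.integer(want), as.integer(have)))
    stop("barcode digits do not match the substituent set ",
         "(expected multiset ", paste(want, collapse = ""), ")",
         call. = FALSE)
}

#' Build 3D conformers of one isomer
#'
#' Grafts the substituents onto the symmetrised scaffold template at the
#' barcode's positions, generates `n_conf` starting geometries differing in
#' the substituent torsions about their exit bonds (the first is the
#' untwisted graft; the rest are drawn from the seeded RNG), relaxes each
#' with the chosen force field, removes duplicates (RMSD below
#' `dedup_rmsd` after alignment) and keeps the `keep` lowest-energy
#' structures.
#'
#' For a chiral barcode the geometry is built for the reference member of
#' the enantiomer pair and mirrored (with the matching position
#' relabelling) for the partner, so enantiomer structures are exact mirror
#' images with identical energies.
#'
#' @param barcode Canonical isomer barcode (canonicalised internally).
#' @param s A [substituent_set()].
#' @param n_conf Number of starting conformers N (default 10).
#' @param keep Number of lowest-energy conformers M to retain (default 1).
#' @param seed RNG seed for the torsion sampling (default 42).
#' @param forcefield `"MMFF94"` (default), `"UFF"`, `"GAFF"` or
#'   `"Ghemical"`.
#' @param steps,crit Minimiser step limit and convergence criterion.
#' @param dedup_rmsd Duplicate threshold in Angstrom (default 0.1).
#' @return An object of class `bv_conformers`: a list of [bv_structure]s
#'   sorted by energy, with fields `barcode`, `n_requested`, `kept`.
#' @export
build_isomer <- function(barcode, s, n_conf = 10, keep = 1, seed = 42,
                         forcefield = "MMFF94", steps = 50000, crit = 1e-10,
                         dedup_rmsd = 0.1) {
  forcefield <- .match_forcefield(forcefield)
  b <- canonical_form(barcode)
  b_codes <- .barcode_to_int(b)
  .validate_barcode_set(b_codes, s)
  cls <- classify_chirality(b)
  if (cls$chirality == "chiral" && b < cls$partner) {
    # build the reference member and mirror it
    ref <- build_isomer(cls$partner, s, n_conf = n_conf, keep = keep,
                        seed = seed, forcefield = forcefield, steps = steps,
                        crit = crit, dedup_rmsd = dedup_rmsd)
    return(.mirror_batch(ref, b))
  }
  sub_pos <- which(b_codes > 0L)
  rolls <- matrix(0, nrow = max(n_conf, 1L), ncol = length(sub_pos))
  if (n_conf > 1L && length(sub_pos)) {
    rolls[-1L, ] <- .with_seed(seed, {
      matrix(runif((n_conf - 1L) * length(sub_pos), 0, 2 * pi),
             nrow = n_conf - 1L)
    })
  }
  cand <- list()
  for (i in seq_len(max(n_conf, 1L))) {
    g <- .graft_barcode(b_codes, s, rolls = rolls[i, ])
    mol <- list(elements = g$elements, coords = g$coords, bonds = g$bonds)
    opt <- .ob_minimize(mol, forcefield, steps = steps, crit = crit)
    e <- .ob_energy(opt, forcefield)
    cand[[i]] <- new_bv_structure(
      elements = opt$elements, coords = opt$coords, bonds = g$bonds,
      barcode = b, position_map = 1:10, attachment_map = g$attachment,
      energy = e, energy_unit = "kJ/mol", provenance = "force-field")
  }
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "energy"))]
  kept <- list()
  for (stc in cand) {
    dup <- any(vapply(kept, function(k) structure_rmsd(k, stc) < dedup_rmsd,
                      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- stc
    if (length(kept) >= keep) break
  }
  out <- list(structures = kept, barcode = b, n_requested = n_conf,
              kept = length(kept), forcefield = forcefield)
  class(out) <- "bv_conformers"
  out
}

#' @export
print.bv_conformers <- function(x, ...) {
  cat("Conformer batch for ", x$barcode, " (", describe_barcode(x$barcode),
      "): ", x$kept, " kept of ", x$n_requested, " requested [",
      x$forcefield, "]\n", sep = "")
  invisible(x)
}

#' Best structure of a conformer batch
#' @param batch A `bv_conformers` object.
#' @return The lowest-energy [bv_structure].
#' @export
best_structure <- function(batch) {
  stopifnot(inherits(batch, "bv_conformers"), batch$kept >= 1L)
  batch$structures[[1L]]
}

# seeded evaluation without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# mirror a whole conformer batch onto the enantiomer barcode b
.mirror_batch <- function(ref, b) {
  out <- list(structures = lapply(ref$structures, .mirror_to_partner, b = b),
              barcode = b, n_requested = ref$n_requested, kept = ref$kept,
              forcefield = ref$forcefield, mirrored_from = ref$barcode)
  class(out) <- "bv_conformers"
  out
}

# mirror a built structure and relabel positions so its barcode becomes the
# enantiomer partner b
.mirror_to_partner <- function(st, b) {
  ref_codes <- .barcode_to_int(st$barcode)
  # find the rotation that carries sigma(ref) onto b
  perm <- BV_SIGMA
  for (j in 0:2) {
    if (identical(.barcode_to_string(.perm_apply(ref_codes, perm)), b)) break
    perm <- .perm_compose(perm, BV_RHO)
    if (j == 2L)
      stop("internal error: partner barcode is not a rotation of the mirror",
           call. = FALSE)
  }
  coords <- st$coords
  coords[, 1L] <- -coords[, 1L]
  new_pm <- st$position_map[perm]
  old_att_pos <- as.integer(names(st$attachment_map))
  new_att_pos <- vapply(old_att_pos, function(p) which(perm == p)[[1L]],
                        integer(1))
  att <- setNames(unname(st$attachment_map), as.character(new_att_pos))
  att <- att[order(as.integer(names(att)))]
  new_bv_structure(elements = st$elements, coords = coords, bonds = st$bonds,
                   barcode = b, position_map = new_pm, attachment_map = att,
                   energy = st$energy, energy_unit = st$energy_unit,
                   provenance = st$provenance)
}

#' Build every isomer of a substitution pattern
#'
#' Runs [build_isomer()] over all canonical barcodes of the pattern.
#' Failures are collected per isomer rather than aborting the batch.
#'
#' @inheritParams build_isomer
#' @param progress Emit a message per isomer.
#' @return Named list (by barcode) of `bv_conformers`; failed isomers carry
#'   a `bv_build_error` record instead, and the result has an attribute
#'   `errors` with their barcodes.
#' @export
build_isomers <- function(s, n_conf = 10, keep = 1, seed = 42,
                          forcefield = "MMFF94", steps = 50000, crit = 1e-10,
                          dedup_rmsd = 0.1, progress = FALSE) {
  barcodes <- enumerate_isomers(s)
  # build reference enantiomers first so partners reuse their geometry
  out <- vector("list", length(barcodes))
  names(out) <- barcodes
  for (b in rev(barcodes)) {  # descending: reference members come first
    if (progress) message("building ", b, " (", describe_barcode(b), ")")
    cls <- classify_chirality(b)
    out[[b]] <- tryCatch({
      ref <- if (cls$chirality == "chiral" && b < cls$partner)
        out[[cls$partner]]
      if (inherits(ref, "bv_conformers")) {
        .mirror_batch(ref, b)  # reuse the already-built reference member
      } else {
        build_isomer(b, s, n_conf = n_conf, keep = keep, seed = seed,
                     forcefield = forcefield, steps = steps, crit = crit,
                     dedup_rmsd = dedup_rmsd)
      }
    }, error = function(e) structure(list(barcode = b,
                                          message = conditionMessage(e)),
                                     class = "bv_build_error"))
  }
  errs <- names(out)[vapply(out, inherits, logical(1), "bv_build_error")]
  if (length(errs))
    warning("failed to build ", length(errs), " isomer(s): ",
            paste(errs, collapse = ", "), call. = FALSE)
  attr(out, "errors") <- errs
  out
}

#' RMSD between two structures
#'
#' Least-squares superposition (proper rotations only) of two structures
#' with identical atom ordering.
#'
#' @param a,b `bv_structure`s with the same atoms.
#' @return RMSD in Angstrom.
#' @export
structure_rmsd <- function(a, b) {
  stopifnot(identical(a$elements, b$elements))
  P <- sweep(a$coords, 2, colMeans(a$coords))
  Q <- sweep(b$coords, 2, colMeans(b$coords))
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((P %*% rot - Q)^2)))
}

#' Mirror a structure's coordinates
#'
#' Reflects through the yz plane; barcode and maps are left untouched (use
#' for geometric tests; see [build_isomer()] for enantiomer bookkeeping).
#'
#' @param st A `bv_structure`.
#' @return The reflected `bv_structure`.
#' @export
mirror_structure <- function(st) {
  st$coords[, 1L] <- -st$coords[, 1L]
  st
}
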