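# Thin wrappers around the Open Babel command-line tools (obabel,
# obminimize, obenergy), which provide SMILES canonicalisation, 3D
# embedding and force-field minimisation/energies.

#' Is Open Babel available?
#'
#' @return `TRUE` if the `obabel` executable is on the PATH.
#' @export
ob_available <- function() {
  if (is.null(.bv_env$ob_ok))
    .bv_env$ob_ok <- all(nzchar(Sys.which(c("obabel", "obminimize",
                                            "obenergy"))))
  .bv_env$ob_ok
}

.assert_openbabel <- function() {
  if (!ob_available())
    stop("Open Babel (obabel, obminimize, obenergy) is required for this ",
         "operation but was not found on the PATH", call. = FALSE)
}

.ob_run <- function(exe, args, allow_fail = FALSE) {
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!allow_fail && !is.null(status) && status != 0L)
    stop(exe, " failed (status ", status, "): ",
         paste(utils::tail(out, 3L), collapse = " / "), call. = FALSE)
  out
}

#' Canonical SMILES via Open Babel
#'
#' @param smiles A single SMILES string.
#' @return Canonical SMILES string.
#' @export
ob_canonical_smiles <- function(smiles) {
  .assert_openbabel()
  out <- .ob_run("obabel", c(paste0("-:", shQuote(smiles)), "-ocan"),
                 allow_fail = TRUE)
  # drop obabel's banner/diagnostic lines; a successful conversion leaves
  # exactly one "SMILES<tab>name" record
  rec <- out[!grepl("molecule|^=+$|^\\*\\*\\*|Error|Warning|^$", out)]
  can <- trimws(sub("\t.*", "", rec[1L]))
  if (any(grepl("^0 molecules", out)) || !length(rec) || is.na(can) ||
      !nzchar(can))
    stop("could not canonicalise SMILES '", smiles, "'", call. = FALSE)
  can
}

# Embed a SMILES in 3D (deterministic rule-based builder + force-field
# clean-up) and return elements / coordinates / bonds.
.ob_embed_smiles <- function(smiles) {
  .assert_openbabel()
  out <- tempfile(fileext = ".sdf")
  on.exit(unlink(out))
  res <- .ob_run("obabel", c(paste0("-:", shQuote(smiles)), "-O",
                             shQuote(out), "--gen3d", "--ff", "MMFF94"),
                 allow_fail = TRUE)
  if (!file.exists(out) || file.size(out) == 0L)
    stop("Open Babel failed to embed SMILES '", smiles, "': ",
         paste(utils::tail(res, 2L), collapse = " / "), call. = FALSE)
  .read_sdf_molecule(out)
}

# parse the first molecule of an SDF into a plain list
.read_sdf_molecule <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bonds <- unname(cbind(bb[, 1L], bb[, 2L], bb[, 3L]))
  storage.mode(bonds) <- "integer"
  list(elements = elements, coords = coords, bonds = bonds)
}

# write a plain molecule list as an SDF (V2000) through ChemmineR
.write_sdf_molecule <- function(mol, path, title = "bvstereo") {
  n <- length(mol$elements)
  # V2000 atom lines have fixed 10-character coordinate fields (%10.4f)
  ab <- cbind(round(mol$coords, 4L), matrix(0, n, 12))
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:16))
  rownames(ab) <- paste(mol$elements, seq_len(n), sep = "_")
  bb <- mol$bonds[, 1:3, drop = FALSE]
  storage.mode(bb) <- "numeric"
  colnames(bb) <- c("C1", "C2", "C3")
  rownames(bb) <- seq_len(nrow(bb))
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bb))
  sdf <- methods::new("SDF",
                      header = c(Molecule_Name = title, Source = "bvstereo",
                                 Comment = "", Counts_Line = counts),
                      atomblock = ab, bondblock = bb,
                      datablock = character(0))
  ChemmineR::write.SDF(sdf, path)
  invisible(path)
}

BV_FORCEFIELDS <- c("MMFF94", "UFF", "GAFF", "Ghemical")

.match_forcefield <- function(forcefield) {
  match.arg(forcefield, BV_FORCEFIELDS)
}

# minimise an SDF in place; returns the minimised molecule list
.ob_minimize <- function(mol, forcefield = "MMFF94", steps = 50000,
                         crit = 1e-10) {
  .assert_openbabel()
  forcefield <- .match_forcefield(forcefield)
  fin <- tempfile(fileext = ".sdf")
  fout <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(fin, fout)))
  .write_sdf_molecule(mol, fin)
  status <- suppressWarnings(system2(
    "obminimize",
    c("-ff", forcefield, "-cg", "-c", format(crit, scientific = TRUE),
      "-n", format(steps, scientific = FALSE), "-osdf", shQuote(fin)),
    stdout = fout, stderr = FALSE))
  if (!identical(status, 0L) || file.size(fout) == 0L)
    stop("obminimize failed (force field ", forcefield, ")", call. = FALSE)
  out <- .read_sdf_molecule(fout)
  if (length(out$elements) != length(mol$elements))
    stop("obminimize changed the atom count", call. = FALSE)
  out$bonds <- mol$bonds  # keep the authoritative topology
  out
}

# force-field energy in kJ/mol (obenergy reports kcal/mol for MMFF94,
# kJ/mol for UFF/GAFF/Ghemical; the unit is parsed from the output)
.ob_energy <- function(mol, forcefield = "MMFF94") {
  .assert_openbabel()
  forcefield <- .match_forcefield(forcefield)
  fin <- tempfile(fileext = ".sdf")
  on.exit(unlink(fin))
  .write_sdf_molecule(mol, fin)
  out <- .ob_run("obenergy", c("-ff", forcefield, shQuote(fin)),
                 allow_fail = TRUE)
  line <- grep("TOTAL ENERGY", out, value = TRUE)
  if (!length(line))
    stop("obenergy reported no total energy (force field ", forcefield, ")",
         call. = FALSE)
  value <- as.numeric(sub(".*TOTAL ENERGY\\s*=\\s*([-+0-9.eE]+).*", "\\1",
                          line[1L]))
  unit <- if (grepl("kcal", line[1L])) "kcal/mol" else "kJ/mol"
  if (unit == "kcal/mol") value * 4.184 else value
}
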