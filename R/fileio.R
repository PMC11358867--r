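# XYZ output, quantum-chemistry input generation and energy ingestion.

#' Write a structure as an XYZ file
#'
#' Standard XYZ: atom count, a comment line carrying the isomer barcode,
#' then one `element x y z` line per atom with coordinates printed as
#' `%.6f` (bit-exact for a given structure).
#'
#' @param st A [bv_structure].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_xyz <- function(st, file) {
  stopifnot(all(is.finite(st$coords)))
  lines <- c(
    as.character(length(st$elements)),
    st$barcode,
    sprintf("%-2s %14.6f %14.6f %14.6f", st$elements,
            st$coords[, 1], st$coords[, 2], st$coords[, 3]))
  writeLines(lines, file)
  invisible(file)
}

#' Read an XYZ file
#'
#' @param file Path to an XYZ file.
#' @return A list with `elements`, `coords` and `comment` (the raw comment
#'   line, which for files written by [write_xyz()] is the barcode).
#' @export
read_xyz <- function(file) {
  lines <- readLines(file)
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 2L)
    stop("malformed XYZ file: ", file, call. = FALSE)
  fields <- strsplit(trimws(lines[3:(n + 2L)]), "[[:space:]]+")
  elements <- vapply(fields, `[`, character(1), 1L)
  coords <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  list(elements = elements, coords = coords, comment = lines[2L])
}

#' Write a quantum-chemistry input file
#'
#' Template-driven text substitution: the placeholders `{coords}`,
#' `{charge}`, `{multiplicity}` and `{comment}` in the template are
#' replaced.  The bundled default template targets the PBE0-D3/def2-SV(P)
#' level of theory in ORCA syntax.
#'
#' @param st A [bv_structure].
#' @param file Output path.
#' @param template Path to a template file (default: bundled ORCA template).
#' @param charge,multiplicity Molecular charge and spin multiplicity.
#' @return `file`, invisibly.
#' @export
write_qc_input <- function(st, file, template = NULL, charge = 0,
                           multiplicity = 1) {
  stopifnot(all(is.finite(st$coords)))
  if (is.null(template))
    template <- system.file("extdata", "qc_template_orca.inp",
                            package = "bvstereo", mustWork = TRUE)
  txt <- paste(readLines(template), collapse = "\n")
  coords <- paste(sprintf("%-2s %14.6f %14.6f %14.6f", st$elements,
                          st$coords[, 1], st$coords[, 2], st$coords[, 3]),
                  collapse = "\n")
  txt <- gsub("{coords}", coords, txt, fixed = TRUE)
  txt <- gsub("{charge}", as.character(charge), txt, fixed = TRUE)
  txt <- gsub("{multiplicity}", as.character(multiplicity), txt, fixed = TRUE)
  txt <- gsub("{comment}", st$barcode, txt, fixed = TRUE)
  writeLines(txt, file)
  invisible(file)
}

# kJ/mol per Hartree
HARTREE_KJMOL <- 2625.4996

#' Ingest per-isomer energies
#'
#' Reads one energy per isomer barcode from a CSV (columns `barcode`,
#' `energy` and optionally `unit`) or from quantum-chemistry output files
#' (ORCA `FINAL SINGLE POINT ENERGY` or Gaussian `SCF Done` records, in
#' Hartree; the barcode is taken from the file name stem).  Energies are
#' converted to kJ/mol and shifted so the minimum is zero.
#'
#' @param source A data frame, a CSV path, or a character vector of QC
#'   output paths.
#' @param unit Unit of the input energies when not given per-row:
#'   `"kJ/mol"`, `"kcal/mol"`, `"Hartree"` or `"eV"`.
#' @param expected Optional character vector of barcodes that should be
#'   present; missing ones trigger a warning naming them.
#' @return Named numeric vector: relative energy in kJ/mol per barcode
#'   (minimum 0), with attribute `unit_in`.
#' @export
ingest_energies <- function(source, unit = "kJ/mol", expected = NULL) {
  to_kj <- function(x, u) {
    u <- tolower(u)
    fac <- c("kj/mol" = 1, "kcal/mol" = 4.184, "hartree" = HARTREE_KJMOL,
             "ev" = 96.4853)
    if (any(!u %in% names(fac)))
      stop("unknown energy unit(s): ", paste(setdiff(u, names(fac)),
                                             collapse = ", "), call. = FALSE)
    x * unname(fac[u])
  }
  if (is.character(source) && length(source) >= 1L &&
      all(file.exists(source)) && !any(grepl("\\.csv$", source))) {
    # quantum-chemistry output files; barcode from file name stem
    vals <- vapply(source, .parse_qc_energy, numeric(1))
    barcodes <- sub("\\..*$", "", basename(source))
    energies <- to_kj(vals, "hartree")
  } else {
    df <- if (is.data.frame(source)) source else read.csv(source,
                                                          colClasses = "character")
    if (!all(c("barcode", "energy") %in% names(df)))
      stop("energy table must have columns 'barcode' and 'energy'",
           call. = FALSE)
    units <- if ("unit" %in% names(df)) df$unit else rep(unit, nrow(df))
    energies <- to_kj(as.numeric(df$energy), units)
    barcodes <- df$barcode
  }
  if (anyDuplicated(barcodes)) {
    for (b in unique(barcodes[duplicated(barcodes)])) {
      v <- energies[barcodes == b]
      if (diff(range(v)) > 1e-6)
        stop("conflicting energies for barcode ", b, call. = FALSE)
    }
    keepi <- !duplicated(barcodes)
    energies <- energies[keepi]
    barcodes <- barcodes[keepi]
  }
  if (!is.null(expected)) {
    missing <- setdiff(expected, barcodes)
    if (length(missing))
      warning("no energy supplied for ", length(missing), " isomer(s): ",
              paste(missing, collapse = ", "), call. = FALSE)
  }
  rel <- energies - min(energies)
  out <- setNames(rel, barcodes)
  attr(out, "unit_in") <- unit
  out
}

# final electronic energy (Hartree) from an ORCA or Gaussian output
.parse_qc_energy <- function(file) {
  lines <- readLines(file, warn = FALSE)
  orca <- grep("FINAL SINGLE POINT ENERGY", lines, value = TRUE)
  if (length(orca))
    return(as.numeric(sub(".*FINAL SINGLE POINT ENERGY\\s+([-+0-9.eEdD]+).*",
                          "\\1", utils::tail(orca, 1L))))
  gau <- grep("SCF Done", lines, value = TRUE)
  if (length(gau)) {
    val <- sub(".*SCF Done:\\s+E\\([^)]*\\)\\s*=\\s*([-+0-9.eEdD]+).*", "\\1",
               utils::tail(gau, 1L))
    return(as.numeric(sub("[dD]", "e", val)))
  }
  stop("no parseable final energy in ", file, call. = FALSE)
}
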