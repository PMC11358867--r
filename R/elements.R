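# Standard atomic weights (Da) and single-bond covalent radii (Angstrom)
# for the elements a substituent is likely to contain.

BV_ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971,
  Br = 79.904, I = 126.904)

BV_COVALENT_RADIUS <- c(
  H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20,
  Br = 1.20, I = 1.39)

#' Standard atomic masses
#'
#' @param elements Character vector of element symbols.
#' @return Numeric vector of standard atomic weights in Da.
#' @export
atomic_masses <- function(elements) {
  m <- BV_ATOMIC_MASS[elements]
  if (anyNA(m))
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "), call. = FALSE)
  unname(m)
}

.covalent_radius <- function(element) {
  r <- BV_COVALENT_RADIUS[element]
  ifelse(is.na(r), 1.0, unname(r))
}
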