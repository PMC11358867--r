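# Synthetic test inputs: random barcodes, analytic mass distributions with
# known PMI coordinates, mirrored coordinate pairs and synthetic energy
# tables.

#' Generate synthetic test fixtures
#'
#' @param kind One of:
#'   * `"barcodes"`: `n` random barcodes drawn for a substituent count
#'     pattern (`counts`, default `c(1, 1)`), reproducible under `seed`;
#'   * `"pmi-vertices"`: three analytic mass distributions with known PMI
#'     coordinates - a two-point rod (0, 1), a regular hexagon (0.5, 0.5)
#'     and a regular tetrahedron (1, 1);
#'   * `"mirror-pair"`: a random point cloud and its mirror image (with
#'     masses), for dihedral-sign tests;
#'   * `"energies-uniform"`: `n` isomer energies all zero;
#'   * `"energies-two-level"`: two isomers split by RT ln 2 at temperature
#'     `temperature` (population ratio exactly 2:1);
#'   * `"energies-random"`: `n` random energies in 0..20 kJ/mol.
#' @param seed RNG seed (default 1).
#' @param n Number of items where applicable.
#' @param counts Substituent count pattern for `"barcodes"`.
#' @param temperature Temperature (K) for `"energies-two-level"`.
#' @return Fixture object; see the kind descriptions.
#' @export
#' @examples
#' bv_fixture("pmi-vertices")$rod
bv_fixture <- function(kind, seed = 1, n = 10, counts = c(1, 1),
                       temperature = 298) {
  switch(
    kind,
    "barcodes" = .with_seed(seed, {
      digits <- .digit_multiset(counts)
      vapply(seq_len(n), function(i)
        .barcode_to_string(sample(digits)), character(1))
    }),
    "pmi-vertices" = list(
      rod = list(coords = rbind(c(0, 0, -1), c(0, 0, 1)),
                 masses = c(1, 1), npr = c(0, 1)),
      disc = list(coords = cbind(cos(2 * pi * 0:5 / 6),
                                 sin(2 * pi * 0:5 / 6), 0),
                  masses = rep(1, 6), npr = c(0.5, 0.5)),
      sphere = list(coords = rbind(c(1, 1, 1), c(1, -1, -1),
                                   c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3),
                    masses = rep(1, 4), npr = c(1, 1))),
    "mirror-pair" = .with_seed(seed, {
      coords <- matrix(runif(3 * n, -2, 2), ncol = 3)
      masses <- runif(n, 1, 12)
      mirrored <- coords
      mirrored[, 1] <- -mirrored[, 1]
      list(original = list(coords = coords, masses = masses),
           mirrored = list(coords = mirrored, masses = masses))
    }),
    "energies-uniform" = setNames(numeric(n),
                                  head(enumerate_isomers(c(1, 1)), n)),
    "energies-two-level" = setNames(
      c(0, BV_GAS_CONSTANT * temperature * log(2)),
      c("1000000000", "0100000000")),
    "energies-random" = .with_seed(seed, {
      b <- enumerate_isomers(counts)
      setNames(runif(length(b), 0, 20), b)
    }),
    stop("unknown fixture kind '", kind, "'", call. = FALSE))
}
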