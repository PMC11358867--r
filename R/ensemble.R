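# Boltzmann population weighting of isomer ensembles.

BV_GAS_CONSTANT <- 8.314462618e-3  # kJ / (mol K)

#' Boltzmann populations of an isomer ensemble
#'
#' Equilibrium weights p_i = exp(-dE_i / RT) / sum_j exp(-dE_j / RT) over
#' the distinct canonical isomers at temperature T.  Each enantiomer is a
#' separate ensemble member carrying its own weight; enantiomer partners
#' are isoenergetic and therefore equally populated.
#'
#' @param energies Named numeric vector of relative energies in kJ/mol per
#'   canonical barcode (e.g. from [ingest_energies()] or force-field
#'   energies from [build_isomers()]); any constant shift is removed.
#' @param temperature Temperature in K (default 298).
#' @return A data frame of class `bv_population`: `barcode`, `dE`
#'   (kJ/mol, minimum 0), `weight`, `chirality`, `partner`, with attribute
#'   `temperature`.  Rows are sorted by increasing energy.
#' @export
#' @examples
#' e <- c(a = 0, b = BV_GAS_CONSTANT * 298 * log(2))
#' names(e) <- c("0100100000", "0100010000")
#' boltzmann_weights(e)$weight  # 2/3, 1/3
boltzmann_weights <- function(energies, temperature = 298) {
  if (!length(energies)) stop("empty energy map", call. = FALSE)
  if (is.null(names(energies)) || any(!nzchar(names(energies))))
    stop("energies must be named by isomer barcode", call. = FALSE)
  if (any(!is.finite(energies))) stop("energies must be finite", call. = FALSE)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be positive", call. = FALSE)
  dE <- energies - min(energies)
  w <- exp(-dE / (BV_GAS_CONSTANT * temperature))
  w <- w / sum(w)
  cls <- lapply(names(energies), classify_chirality)
  out <- data.frame(
    barcode = names(energies), dE = unname(dE), weight = unname(w),
    chirality = vapply(cls, `[[`, character(1), "chirality"),
    partner = vapply(cls, `[[`, character(1), "partner"),
    stringsAsFactors = FALSE)
  out <- out[order(out$dE, out$barcode), ]
  rownames(out) <- NULL
  attr(out, "temperature") <- temperature
  class(out) <- c("bv_population", class(out))
  out
}

#' Extract relative force-field energies from built isomers
#'
#' @param batches Result of [build_isomers()].
#' @return Named numeric vector of relative energies (kJ/mol, min 0).
#' @export
isomer_energies <- function(batches) {
  batches <- Filter(function(e) inherits(e, "bv_conformers"), batches)
  e <- vapply(batches, function(b) best_structure(b)$energy, numeric(1))
  e - min(e)
}

#' Join Boltzmann weights onto a descriptor table
#'
#' @param pop A `bv_population` from [boltzmann_weights()].
#' @param descriptors A data frame from [pmi_table()] or [ev_table()].
#' @param minority_threshold Populations below this are flagged in the
#'   `minority` column (default 0.001, i.e. 0.1 %).
#' @return The descriptor table with `weight`, `marker_size` (proportional
#'   to weight, max 1) and `minority` columns appended.  Isomers that are
#'   populated but missing from the descriptor table are an error.
#' @export
weighted_descriptor_table <- function(pop, descriptors,
                                      minority_threshold = 0.001) {
  stopifnot(inherits(pop, "bv_population"))
  missing <- setdiff(pop$barcode, descriptors$barcode)
  if (length(missing))
    stop("no descriptor rows for populated isomer(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(descriptors$barcode, pop$barcode)
  if (anyNA(idx))
    stop("no population for descriptor isomer(s): ",
         paste(unique(descriptors$barcode[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  descriptors$weight <- pop$weight[idx]
  descriptors$marker_size <- descriptors$weight / max(pop$weight)
  descriptors$minority <- descriptors$weight < minority_threshold
  descriptors
}

#' Annotate an interconversion network with populations
#'
#' Sets a `population` vertex attribute and attaches a layout hint in the
#' style of a mirror-symmetric network diagram: achiral isomers on the
#' central axis (x = 0), enantiomer pairs mirrored either side, ordered
#' vertically by energy.
#'
#' @param net A network from [build_network()].
#' @param pop A `bv_population` covering exactly the network's nodes.
#' @return The network with vertex attribute `population` and graph
#'   attribute `layout` (matrix of node coordinates).
#' @export
weighted_network <- function(net, pop) {
  stopifnot(inherits(pop, "bv_population"))
  nodes <- igraph::V(net)$name
  if (!setequal(nodes, pop$barcode))
    stop("population table and network node sets differ", call. = FALSE)
  idx <- match(nodes, pop$barcode)
  net <- igraph::set_vertex_attr(net, "population", value = pop$weight[idx])
  chir <- igraph::V(net)$chirality
  partner <- igraph::V(net)$partner
  x <- numeric(length(nodes))
  side <- ifelse(chir == "chiral", ifelse(nodes > partner, 1, -1), 0)
  x <- side
  rank <- rank(pop$dE[idx], ties.method = "first")
  layout <- cbind(x = x, y = -rank)
  net <- igraph::set_graph_attr(net, "layout", layout)
  net
}
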