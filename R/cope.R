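# Cope rearrangement steps and isomer interconversion networks.
#
# Each Cope step takes place on one of the three 1,5-hexadiene "faces" of
# the cage, spanning two arms i and j (the spectator arm is k).  Breaking
# the delta_i-delta_j sigma bond and forming beta_i-beta_j turns the old
# {alpha, beta_i, beta_j} triangle into the new cyclopropane, and the old
# spectator delta_k becomes the new apical carbon.  Tracking atoms through
# the rearrangement gives a position permutation realising the four
# elementary exchanges: alpha -> delta(NP), beta(NP) -> gamma,
# beta(P) -> delta, gamma(P) -> gamma.
#
# The relabelling of the product arms is *not* arbitrary: canonicalisation
# only quotients rotations, so the product labels must preserve the
# scaffold's handedness or chiral products would be recorded as their
# enantiomers.  The base permutation below was validated against an
# embedded 3D scaffold (the new apical carbon keeps all three of its bonds
# through the rearrangement, so the sign of the determinant of its three
# bond vectors cannot change); the other two faces follow by conjugation
# with the C3 rotation, which guarantees a consistent orientation.

# base: face {1,2} (spectator arm 3); new[p] = old[BV_COPE_BASE[p]]
BV_COPE_BASE <- c(10L, 7L, 6L, 5L, 4L, 3L, 2L, 9L, 8L, 1L)

.bv_face_perms <- local({
  rho_inv <- order(BV_RHO)
  conj <- function(p) rho_inv[p[BV_RHO]]
  p12 <- BV_COPE_BASE
  p23 <- conj(p12)
  p13 <- conj(p23)
  list("1,2" = p12, "2,3" = p23, "1,3" = p13)
})

#' The three Cope faces
#'
#' @return Data frame with one row per 1,5-hexadiene face: the participating
#'   arms and the spectator arm.
#' @export
cope_faces <- function() {
  data.frame(face = names(.bv_face_perms),
             arm_i = c(1L, 2L, 1L), arm_j = c(2L, 3L, 3L),
             spectator = c(3L, 1L, 2L), stringsAsFactors = FALSE)
}

.face_perm <- function(face) {
  if (is.numeric(face)) {
    if (!face %in% 1:3) stop("face must be 1, 2 or 3 (or a face name)",
                             call. = FALSE)
    return(.bv_face_perms[[face]])
  }
  p <- .bv_face_perms[[as.character(face)]]
  if (is.null(p))
    stop("unknown Cope face '", face, "'; faces are ",
         paste(names(.bv_face_perms), collapse = ", "), call. = FALSE)
  p
}

#' Apply one Cope rearrangement step
#'
#' @param barcode Any barcode representative (canonicalised on output).
#' @param face Face index 1..3 or name `"1,2"`, `"2,3"`, `"1,3"`.
#' @return The canonical barcode of the product isomer.
#' @export
#' @examples
#' cope_step("1000000000", 1)  # alpha-substituted -> delta-substituted
cope_step <- function(barcode, face) {
  codes <- .barcode_to_int(barcode)
  canonical_form(.perm_apply(codes, .face_perm(face)))
}

#' Products of the three possible Cope steps
#'
#' @param barcode A barcode (any representative).
#' @return Character vector of length 3: the canonical product barcode for
#'   each face (a multiset; degenerate rearrangements reproduce the input).
#' @export
cope_neighbors <- function(barcode) {
  codes <- .barcode_to_int(barcode)
  vapply(.bv_face_perms,
         function(p) canonical_form(.perm_apply(codes, p)),
         character(1), USE.NAMES = FALSE)
}

#' Build the isomer interconversion network
#'
#' Nodes are the canonical isomer barcodes of the substitution pattern;
#' every one of an isomer's three Cope faces contributes one transition.
#' Degenerate rearrangements are stored as self-loops, so each node's face
#' count is exactly 3.
#'
#' The number of faces realising a transition is direction-dependent when
#' the two isomers have different rotational symmetry: a C3-symmetric
#' isomer (rotation-invariant barcode, e.g. the alpha-monosubstituted
#' scaffold) reaches its product through all three faces while the reverse
#' transition uses a single face, satisfying
#' m(u -> v) * |orbit(u)| = m(v -> u) * |orbit(v)|.  Each undirected edge
#' therefore carries `mult_from` and `mult_to` (face counts from the
#' `from` and `to` endpoints respectively) plus `multiplicity` (the
#' from-side count; the two coincide for the usual trivial-stabiliser
#' isomers).
#'
#' @inheritParams compute_S
#' @param node_cap Refuse to build networks larger than this many nodes
#'   (default 2e6, which still admits the parent scaffold's 1,209,600
#'   degenerate barcodes).
#' @return An [igraph][igraph::igraph-package] graph with vertex attributes
#'   `name` (barcode), `chirality` and `partner`, and edge attributes
#'   `multiplicity`, `mult_from`, `mult_to`.
#' @export
#' @examples
#' net <- build_network(1)   # 4 isomers: alpha, beta, gamma, delta
#' igraph::vcount(net)
build_network <- function(s, node_cap = 2e6) {
  n <- count_isomers(s)
  if (n > node_cap)
    stop("substitution pattern has ", n, " isomers, above the node cap of ",
         node_cap, call. = FALSE)
  nodes <- enumerate_isomers(s)
  counts <- lapply(nodes, function(u) table(cope_neighbors(u)))
  names(counts) <- nodes
  rows <- list()
  for (u in nodes) {
    tab <- counts[[u]]
    for (v in names(tab)) {
      if (u > v) next  # emit each unordered pair once
      m_uv <- as.integer(tab[[v]])
      m_vu <- if (u == v) m_uv else as.integer(counts[[v]][[u]])
      rows[[length(rows) + 1L]] <- data.frame(
        from = u, to = v, multiplicity = m_uv,
        mult_from = m_uv, mult_to = m_vu, stringsAsFactors = FALSE)
    }
  }
  cls <- lapply(nodes, classify_chirality)
  igraph::graph_from_data_frame(
    do.call(rbind, rows), directed = FALSE,
    vertices = data.frame(
      name = nodes,
      chirality = vapply(cls, `[[`, character(1), "chirality"),
      partner = vapply(cls, `[[`, character(1), "partner"),
      stringsAsFactors = FALSE))
}

#' Face multiplicity sum per node
#'
#' Internal invariant helper: the summed face counts incident to each node
#' (self-loops counted once) must equal 3, one per Cope face.
#'
#' @param net A network from [build_network()].
#' @return Named integer vector over nodes.
#' @export
face_count_per_node <- function(net) {
  ends <- igraph::ends(net, igraph::E(net), names = TRUE)
  m_from <- igraph::E(net)$mult_from
  m_to <- igraph::E(net)$mult_to
  out <- setNames(integer(igraph::vcount(net)), igraph::V(net)$name)
  for (e in seq_len(nrow(ends))) {
    u <- ends[e, 1L]; v <- ends[e, 2L]
    out[u] <- out[u] + m_from[e]
    if (u != v) out[v] <- out[v] + m_to[e]
  }
  out
}

#' Network construction by breadth-first traversal
#'
#' Alternative constructor used as a cross-check of [build_network()]:
#' starting from one barcode the Cope neighbourhood is expanded until
#' closure.  For a valid implementation the reachable set equals the full
#' enumeration (the network is connected).
#'
#' @inheritParams compute_S
#' @param start Optional starting barcode (defaults to the canonical form
#'   of the digit multiset placed in position order).
#' @return Character vector of reachable canonical barcodes, sorted.
#' @export
network_by_bfs <- function(s, start = NULL) {
  if (is.null(start)) {
    digits <- sort(.digit_multiset(s), decreasing = TRUE)
    start <- canonical_form(digits)
  } else {
    start <- canonical_form(start)
  }
  seen <- new.env(parent = emptyenv())
  assign(start, TRUE, envir = seen)
  queue <- start
  while (length(queue)) {
    b <- queue[[1L]]
    queue <- queue[-1L]
    for (nb in cope_neighbors(b)) {
      if (!exists(nb, envir = seen, inherits = FALSE)) {
        assign(nb, TRUE, envir = seen)
        queue <- c(queue, nb)
      }
    }
  }
  sort(ls(seen))
}

# ---- serialisation ----------------------------------------------------------

#' Write / read an isomer network
#'
#' GraphML round-trips all node and edge attributes (via igraph); the plain
#' edge list is a three-column TSV (`from`, `to`, `multiplicity`) preceded
#' by a node table block is not needed since isolated nodes cannot occur
#' (every isomer has three faces).
#'
#' @param net A network from [build_network()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_network_graphml <- function(net, file) {
  # igraph's GraphML writer rejects NA attribute values
  partner <- igraph::V(net)$partner
  partner[is.na(partner)] <- ""
  net <- igraph::set_vertex_attr(net, "partner", value = partner)
  igraph::write_graph(net, file, format = "graphml")
  invisible(file)
}

#' @rdname write_network_graphml
#' @export
read_network_graphml <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  partner <- igraph::V(g)$partner
  partner[!nzchar(partner)] <- NA_character_
  g <- igraph::set_vertex_attr(g, "partner", value = partner)
  g <- igraph::delete_vertex_attr(g, "id")
  g
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(net, file) {
  ends <- igraph::ends(net, igraph::E(net), names = TRUE)
  df <- data.frame(from = ends[, 1L], to = ends[, 2L],
                   multiplicity = igraph::E(net)$multiplicity,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_network_graphml
#' @export
read_network_edgelist <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer"))
  nodes <- sort(unique(c(df$from, df$to)))
  cls <- lapply(nodes, classify_chirality)
  igraph::graph_from_data_frame(
    df, directed = FALSE,
    vertices = data.frame(
      name = nodes,
      chirality = vapply(cls, `[[`, character(1), "chirality"),
      partner = vapply(cls, `[[`, character(1), "partner"),
      stringsAsFactors = FALSE))
}

#' DOT export for small networks
#'
#' @param net A network from [build_network()].
#' @param file Output path.
#' @param max_nodes Refuse above this size (diagram rendering only).
#' @param hide_loops Drop degenerate self-loop edges from the diagram.
#' @export
write_network_dot <- function(net, file, max_nodes = 100, hide_loops = TRUE) {
  if (igraph::vcount(net) > max_nodes)
    stop("network has ", igraph::vcount(net),
         " nodes; DOT export is limited to ", max_nodes, call. = FALSE)
  if (hide_loops)
    net <- igraph::delete_edges(net, igraph::E(net)[igraph::which_loop(net)])
  igraph::write_graph(net, file, format = "dot")
  invisible(file)
}
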