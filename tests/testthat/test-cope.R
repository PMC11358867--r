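test_that("face permutations are atom-level involutions that realise the four exchanges", {
  perms <- bvstereo:::.bv_face_perms
  expect_identical(length(perms), 3L)
  for (p in perms)
    expect_identical(p[p], 1:10)  # performing the step twice restores atoms
  # mirror-conjugation consistency: reflecting, rearranging on the mirrored
  # face and reflecting back equals the original step
  sigma <- bvstereo:::BV_SIGMA
  conj <- sigma[perms[["1,2"]][sigma]]
  expect_identical(conj, perms[["1,3"]])
  # elementary exchanges on face {1,2} (arms 1 and 2 participate):
  p12 <- perms[["1,2"]]
  to <- function(pos) which(p12 == pos)  # where does position pos end up
  expect_identical(to(1L), 10L)   # alpha -> delta (NP)
  expect_identical(to(8L), 9L)    # beta(arm 3, NP) -> gamma
  expect_identical(to(2L), 7L)    # beta(arm 1, P) -> delta
  expect_identical(to(3L), 6L)    # gamma(P) -> gamma
  expect_identical(to(10L), 1L)   # spectator delta -> alpha
})

test_that("cope_step reproduces the monosubstituted exchange table", {
  alpha <- "1000000000"; beta <- "0100000000"
  gamma <- "0010000000"; delta <- "0001000000"
  # alpha's only outcome is delta, on every face
  expect_identical(unique(cope_neighbors(alpha)), delta)
  # gamma: stays gamma on the two participating faces, beta on the spectator
  expect_identical(sort(cope_neighbors(gamma)), sort(c(gamma, gamma, beta)))
  # beta: gamma when non-participating, delta on the two participating faces
  expect_identical(sort(cope_neighbors(beta)), sort(c(gamma, delta, delta)))
  # parent: all three faces are degenerate
  expect_identical(unique(cope_neighbors("0000000000")), "0000000000")
  expect_error(cope_step(beta, "2,4"), "unknown Cope face")
})

test_that("cope steps conserve the substituent multiset and are reversible", {
  for (b in random_barcodes(15, counts = c(2, 1), seed = 5)) {
    for (f in 1:3) {
      product <- cope_step(b, f)
      expect_identical(sort(bvstereo:::.barcode_to_int(product)),
                       sort(bvstereo:::.barcode_to_int(b)))
    }
    # reversibility at the isomer level: b is among each product's neighbours
    cb <- canonical_form(b)
    for (nb in cope_neighbors(cb))
      expect_true(cb %in% cope_neighbors(nb))
  }
})

test_that("interconversion networks have the right size and are 3-regular in faces", {
  for (n in list(1, 2, 3)) {
    net <- build_network(n)
    expect_identical(as.integer(igraph::vcount(net)), count_isomers(n))
    expect_true(igraph::is_connected(net))
    expect_true(all(face_count_per_node(net) == 3L))
  }
  net4 <- build_network(4)
  expect_identical(as.integer(igraph::vcount(net4)), 72L)
  expect_true(igraph::is_connected(net4))
  # heterodisubstituted network
  net11 <- build_network(c(1, 1))
  expect_identical(as.integer(igraph::vcount(net11)), 30L)
  expect_true(igraph::is_connected(net11))
})

test_that("transition multiplicities obey the orbit-weighted symmetry law", {
  # m(u -> v) |orbit(u)| = m(v -> u) |orbit(v)|; raw equality holds for
  # isomers with trivial rotational stabilisers
  for (counts in list(1, 2)) {
    nodes <- enumerate_isomers(counts)
    for (u in nodes) {
      for (v in unique(cope_neighbors(u))) {
        m_uv <- sum(cope_neighbors(u) == v)
        m_vu <- sum(cope_neighbors(v) == u)
        expect_identical(m_uv * length(bv_orbit(u)),
                         m_vu * length(bv_orbit(v)))
        if (length(bv_orbit(u)) == 3L && length(bv_orbit(v)) == 3L)
          expect_identical(m_uv, m_vu)
      }
    }
  }
  # the C3-symmetric alpha-monosubstituted isomer reaches delta by all
  # three faces, while the reverse transition uses a single face
  expect_identical(sum(cope_neighbors("1000000000") == "0001000000"), 3L)
  expect_identical(sum(cope_neighbors("0001000000") == "1000000000"), 1L)
})

test_that("breadth-first traversal recovers the full enumeration", {
  for (p in list(1, 2, c(1, 1)))
    expect_identical(network_by_bfs(p), enumerate_isomers(p))
})

test_that("the node cap refuses oversized networks by name", {
  expect_error(build_network(rep(1, 9), node_cap = 1000), "1209600")
})

test_that("network serialisation round-trips", {
  net <- build_network(2)
  gml <- tempfile(fileext = ".graphml")
  tsv <- tempfile(fileext = ".tsv")
  dot <- tempfile(fileext = ".dot")
  write_network_graphml(net, gml)
  g2 <- read_network_graphml(gml)
  expect_setequal(igraph::V(g2)$name, igraph::V(net)$name)
  expect_identical(igraph::ecount(g2), igraph::ecount(net))
  expect_equal(sort(igraph::E(g2)$multiplicity),
               sort(igraph::E(net)$multiplicity))
  expect_true(all(face_count_per_node(g2) == 3L))
  expect_identical(
    sum(is.na(igraph::V(g2)$partner)),
    sum(igraph::V(net)$chirality == "achiral"))
  write_network_edgelist(net, tsv)
  g3 <- read_network_edgelist(tsv)
  expect_setequal(igraph::V(g3)$name, igraph::V(net)$name)
  expect_identical(igraph::ecount(g3), igraph::ecount(net))
  write_network_dot(net, dot)
  expect_true(file.size(dot) > 0)
  expect_error(write_network_dot(build_network(3), dot, max_nodes = 10),
               "limited")
  # parent network: one node with a triple self-loop
  net0 <- build_network(integer(0))
  expect_identical(as.integer(igraph::vcount(net0)), 1L)
  expect_identical(face_count_per_node(net0)[[1]], 3L)
})
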