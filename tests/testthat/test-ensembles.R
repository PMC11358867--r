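test_that("Boltzmann weights reproduce the closed forms", {
  u <- boltzmann_weights(setNames(numeric(4), enumerate_isomers(1)))
  expect_equal(u$weight, rep(0.25, 4))
  expect_lt(abs(sum(u$weight) - 1), 1e-12)
  two <- boltzmann_weights(bv_fixture("energies-two-level"))
  expect_equal(sort(two$weight), c(1 / 3, 2 / 3), tolerance = 1e-12)
  # weights decrease with energy
  r <- boltzmann_weights(bv_fixture("energies-random", counts = 2, seed = 4))
  expect_true(all(diff(r$weight) <= 1e-15))
  expect_lt(abs(sum(r$weight) - 1), 1e-12)
})

test_that("weights are invariant to a constant energy shift", {
  e <- bv_fixture("energies-random", counts = 2, seed = 9)
  a <- boltzmann_weights(e)
  b <- boltzmann_weights(e + 123.45)
  expect_equal(a$weight, b$weight, tolerance = 1e-12)
})

test_that("temperature limits behave correctly", {
  e <- bv_fixture("energies-random", counts = 2, seed = 12)
  hot <- boltzmann_weights(e, temperature = 1e6)
  expect_lt(diff(range(hot$weight)), 1e-3)            # near uniform
  cold <- boltzmann_weights(e, temperature = 1)
  expect_gt(max(cold$weight), 1 - 1e-6)               # minimum dominates
  expect_identical(cold$barcode[which.max(cold$weight)],
                   names(e)[which.min(e)])
  expect_error(boltzmann_weights(e, temperature = -5), "positive")
  expect_error(boltzmann_weights(numeric(0)), "empty")
  expect_error(boltzmann_weights(c(1, 2)), "named")
})

test_that("enantiomer partners carry equal weights", {
  bat <- cached_batches(2)
  pop <- boltzmann_weights(isomer_energies(bat))
  chir <- pop[pop$chirality == "chiral", ]
  for (i in seq_len(nrow(chir))) {
    pw <- pop$weight[pop$barcode == chir$partner[i]]
    expect_equal(chir$weight[i], pw, tolerance = 1e-9)
  }
})

test_that("weighted descriptor tables join, scale markers and flag minorities", {
  bat <- cached_batches(2)
  pop <- boltzmann_weights(isomer_energies(bat))
  pt <- pmi_table(bat)
  w <- weighted_descriptor_table(pop, pt)
  expect_identical(nrow(w), nrow(pt))
  expect_equal(max(w$marker_size), 1)
  expect_true(any(w$minority))   # high-energy dimethyl isomers are < 0.1 %
  # uniform weights give equal markers
  upop <- boltzmann_weights(setNames(numeric(15), pt$barcode))
  wu <- weighted_descriptor_table(upop, pt)
  expect_lt(diff(range(wu$marker_size)), 1e-12)
  # populated isomer missing from the descriptors is a hard error
  expect_error(weighted_descriptor_table(pop, pt[-1, ]), pt$barcode[1])
})

test_that("weighted networks annotate populations with a mirrored layout", {
  net <- build_network(1)
  pop <- boltzmann_weights(setNames(numeric(4), enumerate_isomers(1)))
  wn <- weighted_network(net, pop)
  expect_equal(igraph::V(wn)$population, rep(0.25, 4))
  expect_equal(sum(igraph::V(wn)$population), 1)
  bat <- cached_batches(2)
  net2 <- build_network(2)
  pop2 <- boltzmann_weights(isomer_energies(bat))
  wn2 <- weighted_network(net2, pop2)
  layout <- igraph::graph_attr(wn2, "layout")
  expect_identical(sum(layout[, "x"] == 0), 9L)    # achiral axis
  expect_identical(sum(layout[, "x"] > 0), 3L)     # mirrored pairs
  expect_identical(sum(layout[, "x"] < 0), 3L)
  expect_error(weighted_network(net, pop2), "differ")
})
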