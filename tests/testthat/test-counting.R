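test_that("the symmetry factor S matches its worked examples", {
  expect_identical(compute_S(c(3, 1)), 3L)       # unique substituent apical
  expect_identical(compute_S(c(1, 1, 1)), 0L)    # no C3 arrangement
  expect_identical(compute_S(integer(0)), 1L)    # parent: all-H barcode
  expect_identical(compute_S(c(3, 3)), 6L)       # two full-arm triples
})

test_that("S agrees with the brute-force count of rotation-invariant barcodes", {
  patterns <- list(integer(0), 1, 2, 3, 4, c(1, 1), c(2, 1), c(3, 1),
                   c(3, 3), c(3, 3, 3), c(1, 1, 1), c(9), c(3, 1, 1))
  for (p in patterns) {
    scan <- scan_isomers(p)
    expect_identical(as.integer(scan$n_rho_invariant), compute_S(p))
    expect_true(compute_S(p) %in% c(0L, 1L, 3L, 6L))
  }
})

test_that("closed-form isomer counts reproduce the worked examples", {
  expect_identical(count_isomers(c(1, 1, 1)), 240L)
  expect_identical(count_isomers(c(3, 1)), 282L)
  expect_identical(count_isomers(2), 15L)
  expect_identical(count_isomers(3), 42L)
  expect_identical(count_isomers(4), 72L)
  expect_identical(count_isomers(rep(1, 9)), 1209600L)  # ten distinct types
  expect_identical(count_isomers(integer(0)), 1L)
  expect_identical(count_isomers(1), 4L)  # alpha, beta, gamma, delta
})

test_that("enumeration agrees exactly with the closed form", {
  for (p in list(integer(0), 1, 2, 3, 4, c(1, 1), c(2, 1), c(1, 1, 1),
                 c(3, 1))) {
    b <- enumerate_isomers(p)
    expect_identical(length(b), as.integer(count_isomers(p)))
    expect_identical(b, sort(b))           # sorted output
    expect_identical(anyDuplicated(b), 0L)
    # every element is canonical, and no two share a rotation orbit
    expect_true(all(vapply(b, canonical_form, character(1)) == b))
  }
})

test_that("there are exactly 42 substitution variations", {
  v <- enumerate_substitution_variations()
  expect_identical(nrow(v), 42L)
  expect_identical(v$N_iso[v$partition == "10"], 1L)
  expect_identical(v$N_iso[v$partition == "7+1+1+1"], 240L)
  expect_true(all(v$S %in% c(0L, 1L, 3L, 6L)))
})

test_that("substituent sets validate and merge structurally identical entries", {
  s <- substituent_set(c("C", "C"), c(1, 1))
  expect_identical(s$count, 2L)            # merged into one methyl type
  expect_identical(n_hydrogen(s), 8L)
  expect_error(substituent_set("C", 11), "at most 10")
  expect_error(substituent_set("C", 0), "positive")
  # equivalent SMILES spellings of ethyl merge
  s2 <- substituent_set(c("CC", "C(C)"), c(1, 2))
  expect_identical(length(s2$smiles), 1L)
  expect_identical(s2$count, 3L)
})

test_that("CLI-style substituent specs parse", {
  s <- parse_substituent_spec(c("C:2", "O"))
  expect_identical(s$count, c(2L, 1L))
  expect_identical(count_isomers(s), count_isomers(c(2, 1)))
})
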