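test_that("PMI reproduces the analytic vertex cases", {
  fx <- bv_fixture("pmi-vertices")
  rod <- pmi(fx$rod)
  expect_equal(c(rod$NPR1, rod$NPR2), c(0, 1), tolerance = 1e-9)
  expect_true(rod$collinear)
  disc <- pmi(fx$disc)
  expect_equal(c(disc$NPR1, disc$NPR2), c(0.5, 0.5), tolerance = 1e-9)
  sphere <- pmi(fx$sphere)
  expect_equal(c(sphere$NPR1, sphere$NPR2), c(1, 1), tolerance = 1e-9)
})

test_that("PMI is invariant under rigid rotation and translation", {
  fx <- bv_fixture("mirror-pair", n = 12, seed = 2)$original
  ref <- pmi(fx)
  qr_rot <- qr.Q(qr(matrix(c(0.1, -0.4, 0.9, 0.5, 0.2, -0.3, 0.7, 0.8, 0.1),
                           3, 3)))
  moved <- list(coords = sweep(fx$coords %*% qr_rot, 2, c(-3, 5, 11)),
                masses = fx$masses)
  got <- pmi(moved)
  expect_equal(got$NPR1, ref$NPR1, tolerance = 1e-9)
  expect_equal(got$NPR2, ref$NPR2, tolerance = 1e-9)
})

test_that("NPR bounds hold on every built structure", {
  for (batch in cached_batches(2)) {
    p <- pmi(best_structure(batch))
    expect_lte(p$NPR1, p$NPR2 + 1e-12)
    expect_lte(p$NPR2, 1 + 1e-12)
    expect_gte(p$NPR1 + p$NPR2, 1 - 1e-12)   # perpendicular-axis bound
    expect_true(p$SNPR >= 1 - 1e-12 && p$SNPR <= 2 + 1e-12)
  }
})

test_that("mirror-image coordinates negate theta and preserve r and phi", {
  st <- best_structure(cached_batches(2)[["0100010000"]])  # chiral beta,gamma'
  ev <- exit_vectors(st, 2, 6)
  evm <- exit_vectors(mirror_structure(st), 2, 6)
  expect_equal(evm$theta, -ev$theta, tolerance = 1e-9)
  expect_equal(evm$r, ev$r, tolerance = 1e-9)
  expect_equal(evm$phi1, ev$phi1, tolerance = 1e-9)
  expect_equal(evm$phi2, ev$phi2, tolerance = 1e-9)
  # argument order does not change the reported sign
  expect_equal(exit_vectors(st, 6, 2)$theta, ev$theta)
})

test_that("all_pairs_ev yields one record per substituent pair", {
  st2 <- best_structure(cached_batches(2)[["0100100000"]])
  expect_identical(nrow(all_pairs_ev(st2)), 1L)
  # a tetramethyl isomer has choose(4, 2) = 6 pairs
  b4 <- enumerate_isomers(4)[1]
  st4 <- best_structure(build_isomer(b4, me_set(4), n_conf = 1))
  expect_identical(nrow(all_pairs_ev(st4)), 6L)
  expect_error(exit_vectors(st2, 2, 3), "no substituent")
  expect_error(all_pairs_ev(best_structure(build_isomer(
    "1000000000", me_set(1), n_conf = 1))), "at least two")
})

test_that("the plane-angle convention switch returns the supplement", {
  st <- best_structure(cached_batches(2)[["0100100000"]])
  a <- exit_vectors(st, 2, 5, phi_convention = "away")
  b <- exit_vectors(st, 2, 5, phi_convention = "complement")
  expect_equal(a$phi1 + b$phi1, 180)
  expect_equal(a$phi2 + b$phi2, 180)
})

test_that("descriptor tables cover every isomer and pair", {
  bat <- cached_batches(2)
  pt <- pmi_table(bat)
  expect_identical(nrow(pt), 15L)
  expect_setequal(pt$barcode, enumerate_isomers(2))
  et <- ev_table(bat)
  expect_identical(nrow(et), 15L)  # one methyl pair per isomer
  f <- tempfile(fileext = ".csv")
  write_descriptor_csv(et, f, rounded = TRUE)
  back <- read.csv(f, colClasses = c(barcode = "character"))
  expect_true(all(back$theta == round(back$theta)))
  expect_true(all(abs(back$r * 10 - round(back$r * 10)) < 1e-9))
})

test_that("shape-space plots build from descriptor tables", {
  bat <- cached_batches(2)
  pt <- pmi_table(bat)
  et <- ev_table(bat)
  pop <- boltzmann_weights(isomer_energies(bat))
  expect_s3_class(plot_pmi(pt, label = TRUE), "ggplot")
  expect_s3_class(plot_pmi(weighted_descriptor_table(pop, pt)), "ggplot")
  expect_s3_class(plot_ev(et), "ggplot")
  expect_s3_class(plot_ev(et, absolute = TRUE, theta_range = c(0, 180)),
                  "ggplot")
  expect_s3_class(plot_ev_phi(weighted_descriptor_table(pop, et)), "ggplot")
})
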