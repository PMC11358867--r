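test_that("the core template is a sane C3v bullvalene", {
  tm <- bv_core_template()
  expect_identical(tm$elements, c(rep("C", 10), rep("H", 10)))
  expect_identical(sort(tm$position_map), 1:10)  # bijective onto carbons
  d <- function(i, j) sqrt(sum((tm$coords[i, ] - tm$coords[j, ])^2))
  # cyclopropane delta-delta bonds and olefinic beta=gamma bonds
  for (p in list(c(4, 7), c(7, 10), c(4, 10)))
    expect_lt(abs(d(p[1], p[2]) - 1.5), 0.1)
  for (p in list(c(2, 3), c(5, 6), c(8, 9)))
    expect_lt(abs(d(p[1], p[2]) - 1.34), 0.1)
  # alpha has exactly three carbon neighbours, all beta positions
  bonds <- tm$bonds
  nb <- c(bonds[bonds[, 1] == 1L, 2], bonds[bonds[, 2] == 1L, 1])
  expect_setequal(nb[nb <= 10], c(2L, 5L, 8L))
})

test_that("grafting conserves composition and scaffold topology", {
  bat <- cached_batches(2)
  st <- best_structure(bat[["0100100000"]])  # beta,beta'
  expect_identical(molecular_formula(st), "C12H14")
  expect_identical(sum(st$elements == "C"), 12L)  # 10 + one per methyl
  expect_identical(sort(as.integer(names(st$attachment_map))), c(2L, 5L))
  # scaffold bond lengths survive minimisation
  d <- function(i, j) sqrt(sum((st$coords[i, ] - st$coords[j, ])^2))
  for (p in list(c(4, 7), c(7, 10), c(4, 10)))
    expect_lt(abs(d(p[1], p[2]) - 1.5), 0.12)
})

test_that("building the parent with an empty set reproduces the template", {
  bat <- build_isomer("0000000000", substituent_set(), n_conf = 1)
  st <- best_structure(bat)
  expect_identical(molecular_formula(st), "C10H10")
  expect_lt(structure_rmsd(st, bv_core_template()), 0.1)
  expect_true(is.finite(st$energy))
})

test_that("identical barcode, set and seed give identical coordinates", {
  s <- me_set(2)
  b1 <- build_isomer("0100010000", s, n_conf = 3, seed = 42)
  b2 <- build_isomer("0100010000", s, n_conf = 3, seed = 42)
  expect_identical(best_structure(b1)$coords, best_structure(b2)$coords)
})

test_that("enantiomer structures are isoenergetic exact mirror images", {
  bat <- cached_batches(2)
  chiral <- Filter(function(b) inherits(b, "bv_conformers") &&
                     classify_chirality(b$barcode)$chirality == "chiral", bat)
  expect_identical(length(chiral), 6L)
  seen <- character()
  for (b in chiral) {
    partner <- classify_chirality(b$barcode)$partner
    if (partner %in% seen) next
    seen <- c(seen, b$barcode)
    st <- best_structure(b)
    stp <- best_structure(bat[[partner]])
    expect_lt(abs(st$energy - stp$energy), 1e-3 * 4.184)  # isoenergetic
    expect_lt(structure_rmsd(mirror_structure(st), stp), 0.1)
  }
})

test_that("grafting errors are informative", {
  expect_error(substituent_set("not-a-smiles"),
               "canonicalise|embed")  # rejected at canonicalisation
  s_co2 <- substituent_set("O=C=O")
  expect_error(build_isomer("1000000000", s_co2, n_conf = 1),
               "no free valence")
  expect_error(build_isomer("0100000000", me_set(2), n_conf = 1),
               "do not match")       # one substituent but the set has two
})

test_that("XYZ output round-trips and carries the barcode", {
  st <- best_structure(cached_batches(2)[["0100100000"]])
  f <- tempfile(fileext = ".xyz")
  write_xyz(st, f)
  lines <- readLines(f)
  expect_identical(lines[1], as.character(length(st$elements)))
  expect_identical(lines[2], "0100100000")
  back <- read_xyz(f)
  expect_identical(back$elements, st$elements)
  expect_lt(max(abs(back$coords - st$coords)), 1e-6)
  # parent scaffold: 20 atoms
  f2 <- tempfile(fileext = ".xyz")
  write_xyz(bv_core_template(), f2)
  expect_identical(readLines(f2)[1], "20")
})

test_that("QC input generation substitutes the template placeholders", {
  st <- best_structure(cached_batches(2)[["0100100000"]])
  f <- tempfile(fileext = ".inp")
  write_qc_input(st, f, charge = 0, multiplicity = 1)
  txt <- readLines(f)
  expect_false(any(grepl("{coords}", txt, fixed = TRUE)))
  expect_true(any(grepl("0 1", txt, fixed = TRUE)))
  expect_true(any(grepl("0100100000", txt, fixed = TRUE)))
  expect_identical(sum(grepl("^C ", txt)), 12L)
  # custom template
  tf <- tempfile()
  writeLines("q={charge} m={multiplicity}\n{coords}", tf)
  write_qc_input(st, f, template = tf, charge = -1, multiplicity = 2)
  expect_true(any(grepl("q=-1 m=2", readLines(f))))
})

test_that("energy ingestion converts units and reports missing isomers", {
  df <- data.frame(barcode = c("a", "b"), energy = c(1, 1))
  expect_identical(as.numeric(ingest_energies(df)), c(0, 0))
  dfh <- data.frame(barcode = c("a", "b"), energy = c(0, 1),
                    unit = "Hartree")
  expect_equal(unname(sort(ingest_energies(dfh))), c(0, 2625.4996))
  expect_warning(
    ingest_energies(data.frame(barcode = "x", energy = 0),
                    expected = c("x", "0100100000")),
    "0100100000")
  expect_error(
    ingest_energies(data.frame(barcode = c("x", "x"), energy = c(0, 5))),
    "conflicting")
  # quantum-chemistry output parsing (ORCA and Gaussian styles)
  d <- tempfile(); dir.create(d)
  writeLines(c("...", "FINAL SINGLE POINT ENERGY      -465.123456789", ".."),
             file.path(d, "0100100000.out"))
  writeLines(" SCF Done:  E(RPBE1PBE) =  -465.623456789     A.U. after 9 cycles",
             file.path(d, "0100010000.log"))
  e <- ingest_energies(list.files(d, full.names = TRUE))
  expect_setequal(names(e), c("0100100000", "0100010000"))
  expect_equal(max(e), 0.5 * 2625.4996, tolerance = 1e-6)
  expect_error(ingest_energies({
    f <- file.path(d, "junk.out"); writeLines("nothing", f); f
  }), "no parseable")
})
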