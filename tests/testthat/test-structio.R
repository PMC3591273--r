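test_that("read_pdb parses ATOM records, models, and infers elements", {
  txt <- c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      12.560   6.351  -6.510  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      13.276   5.031  -6.300  1.00  0.00           C")
  st <- read_pdb(txt)[[1]]
  expect_equal(n_atoms(st), 3L)
  expect_equal(st$atoms$name, c("N", "CA", "C"))
  expect_equal(st$atoms$x[2], 12.560)

  # two models
  two <- c("MODEL     1", txt, "ENDMDL", "MODEL     2", txt, "ENDMDL")
  expect_length(read_pdb(two, model_policy = "all"), 2L)
  expect_length(read_pdb(two, model_policy = "first"), 1L)

  # blank element column: inferred from the atom-name field.
  # Expected values frozen from an independent parser (biotite) on this
  # fixture: " CA " -> C (alpha carbon), "FE  " at column 13 -> FE.
  blank <- c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2 FE   HEM A   2       1.000   2.000   3.000  1.00  0.00")
  stb <- read_pdb(blank)[[1]]
  expect_equal(stb$atoms$element, c("C", "FE"))
})

test_that("read_pdb error paths name the problem", {
  expect_error(read_pdb(""), "empty|no ATOM")
  expect_error(read_pdb("HEADER    NOTHING"), "no ATOM")
  bad <- "ATOM      1  CA  ALA A   1      xx.104   6.134  -6.504  1.00  0.00"
  expect_error(read_pdb(bad), "line 1")
})

test_that("alt_loc policy keeps highest occupancy, ties alphabetical", {
  txt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C")
  st <- read_pdb(txt)[[1]]
  expect_equal(n_atoms(st), 2L)
  expect_equal(st$atoms$x[st$atoms$name == "CA"], 1.0)   # occupancy 0.60 wins
  expect_equal(st$atoms$x[st$atoms$name == "CB"], 3.0)   # tie: alt_loc A wins
  # determinism
  expect_identical(read_pdb(txt)[[1]]$atoms, st$atoms)
})

test_that("waters are dropped, other HETATM retained and strippable", {
  txt <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A 101       5.000   0.000   0.000  1.00  0.00           O",
    "HETATM    3  C1  LIG A 201       6.000   0.000   0.000  1.00  0.00           C")
  st <- read_pdb(txt)[[1]]
  expect_equal(n_atoms(st), 2L)
  expect_true(any(st$atoms$is_het))
  expect_equal(n_atoms(strip_hetero(st)), 1L)
})

test_that("assign_radii uses the shipped Bondi table and rejects unknowns", {
  st <- atom_pair(5)
  expect_equal(st$atoms$vdw_radius, c(1.70, 1.70))
  tab <- read_radius_table(system.file("extdata", "vdw_bondi.csv",
                                       package = "pocketeer"))
  expect_equal(unname(tab[["C"]]), 1.70)
  bad <- st
  bad$atoms$element[2] <- "XX"
  expect_error(assign_radii(bad), "XX")
})

test_that("resolve_selector finds residues and honours insertion codes", {
  st <- fx_mini()$structure
  res <- resolve_selector(st, "A:4")
  expect_equal(nrow(res), 5L)                     # ALA heavy atoms
  expect_error(resolve_selector(st, "C:4"), "C:4")
  # insertion-code residue distinct from plain-number residue
  txt <- c(
    "ATOM      1  CA  ALA A  52       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A  52A      2.000   0.000   0.000  1.00  0.00           C")
  st2 <- read_pdb(txt)[[1]]
  expect_equal(resolve_selector(st2, selector("A", 52, "A"))$x, 2.0)
  expect_equal(resolve_selector(st2, selector("A", 52))$x, 0.0)
})

test_that("write -> read round trip preserves atoms to PDB precision", {
  for (st in list(fx_mini()$structure, fx_flask()$structure)) {
    lines <- write_pdb(st)
    back <- read_pdb(paste(lines, collapse = "\n"))[[1]]
    expect_equal(n_atoms(back), n_atoms(st))
    expect_equal(back$atoms$name, st$atoms$name)
    expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                        as.matrix(st$atoms[, c("x", "y", "z")]))), 1e-3 + 1e-9)
  }
  # multi-model write/read
  multi <- write_pdb(list(fx_mini()$structure, fx_mini()$structure))
  expect_length(read_pdb(paste(multi, collapse = "\n"), "all"), 2L)
})
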