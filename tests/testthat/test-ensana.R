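# build a bound complex: mini-protein + 5-atom hetero ligand placed near
# a chosen residue
bound_complex <- function(offset = 4) {
  st <- fx_mini()$structure
  ca <- resolve_selector(st, "A:6")
  lig_xyz <- cbind(ca$x[1] + c(0, 1.5, 3.0, 1.5, 1.5),
                   ca$y[1] + offset + c(0, 0, 0, 1.5, 0),
                   ca$z[1] + c(0, 0, 0, 0, 1.5))
  lig <- pocketeer:::.lattice_atoms(lig_xyz, chain = "X", resno = 90L,
                                    resname = "LIG")
  lig$is_het <- TRUE
  st$atoms <- rbind(st$atoms, lig)
  st$atoms$serial <- seq_len(nrow(st$atoms))
  assign_radii(st)
}

test_that("derive_interface applies the ligand-contact rule", {
  bc <- bound_complex()
  iface <- derive_interface(bc, 5.0)
  # independent oracle: plain distance loop over the same coordinates
  a <- bc$atoms
  lig <- a[a$is_het, ]
  prot <- a[!a$is_het, ]
  hit <- rep(FALSE, nrow(prot))
  for (i in seq_len(nrow(lig)))
    hit <- hit | sqrt((prot$x - lig$x[i])^2 + (prot$y - lig$y[i])^2 +
                        (prot$z - lig$z[i])^2) <= 5.0
  expected <- unique(paste0(prot$chain_id[hit], ":", prot$residue_number[hit]))
  expect_setequal(vapply(iface$residues, format, ""), expected)

  expect_error(derive_interface(fx_mini()$structure), "no HETATM")
  expect_error(derive_interface(bc, 0), "positive")
  expect_error(derive_interface(bound_complex(offset = 40), 5.0),
               "no protein contacts")
})

test_that("min_irmsd is zero on identity and rigid motion, min over refs", {
  st <- fx_mini()$structure
  iface <- derive_interface(bound_complex(), 5.0)
  expect_lt(min_irmsd(st, list(st), iface), 1e-8)

  rot <- st
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  th <- 0.8
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3,
              byrow = TRUE)
  x2 <- xyz %*% R
  rot$atoms$x <- x2[, 1] + 3; rot$atoms$y <- x2[, 2]; rot$atoms$z <- x2[, 3]
  expect_lt(min_irmsd(rot, list(st), iface), 1e-8)
  expect_lt(min_irmsd(rot, list(st), iface, superposition = "local"), 1e-8)

  # three references, conformation equals ref2 exactly
  perturbed <- st
  perturbed$atoms$x <- perturbed$atoms$x + rnorm(nrow(st$atoms), sd = 0.5)
  v <- min_irmsd(st, list(perturbed, st, perturbed), iface)
  expect_lt(v, 1e-8)
  per_ref <- attr(v, "per_reference")
  expect_length(per_ref, 3L)
  expect_true(all(v <= per_ref + 1e-12))
  expect_gt(per_ref[1], 0)

  # atom mismatch is reported
  broken <- st
  broken$atoms <- broken$atoms[broken$atoms$name != "CB" |
                                 broken$atoms$residue_number != 6, ]
  expect_error(min_irmsd(st, list(broken), iface), "A:6/CB")
})

test_that("backbone scope restricts the iRMSD atom set", {
  st <- fx_mini()$structure
  iface_h <- derive_interface(bound_complex(), 5.0, atom_scope = "heavy")
  iface_b <- iface_h
  iface_b$atom_scope <- "backbone"
  ch <- pocketeer:::.interface_coords(st, iface_h)
  cb <- pocketeer:::.interface_coords(st, iface_b)
  expect_equal(nrow(cb), 4L * length(iface_b$residues))
  expect_gt(nrow(ch), nrow(cb))
})

test_that("Shrake-Rupley areas: isolated spheres are exact", {
  # two isolated atoms (C and N) well apart: area = 4 pi (r + probe)^2
  st <- atom_pair(50, elements = c("C", "N"))
  a <- shrake_rupley_sasa(st)
  expect_equal(a[1], 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
  expect_equal(a[2], 4 * pi * (1.55 + 1.4)^2, tolerance = 1e-9)

  # hSASA of a "pocket" lining both atoms: closed-form sphere-area ratio
  pocket <- list(lining_rows = 1:2)
  h <- pocket_hsasa(st, pocket)
  expect_equal(h$pct_hsasa, 100 * a[1] / (a[1] + a[2]), tolerance = 1e-9)

  # all-carbon lining is 100% hydrophobic
  fl <- fx_flask()$structure
  ps <- detect_pockets(fl, "A:1")
  expect_equal(pocket_hsasa(fl, ps$pockets[[1]])$pct_hsasa, 100)
  expect_error(pocket_hsasa(fl, list(lining_rows = integer(0))), "lining")
})

test_that("pct_hsasa is invariant under rigid motion", {
  fl <- fx_flask()$structure
  ps <- detect_pockets(fl, "A:1")
  h0 <- pocket_hsasa(fl, ps$pockets[[1]], n_points = 240)
  rot <- fl
  th <- 0.3
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3,
              byrow = TRUE)
  x2 <- as.matrix(fl$atoms[, c("x", "y", "z")]) %*% R
  rot$atoms$x <- x2[, 1] + 2; rot$atoms$y <- x2[, 2]; rot$atoms$z <- x2[, 3]
  suppressWarnings(ps2 <- detect_pockets(rot, "A:1"))
  h1 <- pocket_hsasa(rot, ps2$pockets[[1]], n_points = 240)
  expect_equal(h1$pct_hsasa, h0$pct_hsasa, tolerance = 1e-6)  # all-C: both 100
})

test_that("cumulative volume curves follow the contract", {
  c0 <- cumulative_volume_curve(c(0, 0, 0))
  expect_equal(c0$fraction[c0$volume == 0], 1)
  expect_true(all(diff(c0$fraction) <= 0))
  c1 <- cumulative_volume_curve(c(10, 20))
  expect_equal(c1$fraction[c1$volume == 20], 0.5)   # fraction >= 15 is 0.5
  expect_equal(c1$fraction[c1$volume == 0], 1)
  expect_true(all(diff(c1$fraction) <= 0))
  expect_error(cumulative_volume_curve(numeric(0)))
})

test_that("secondary structure classifies the helical mini-protein", {
  ss <- secondary_structure(fx_mini()$structure)
  interior <- !is.na(ss$phi) & !is.na(ss$psi)
  expect_true(all(ss$ss[interior] == "H"))
  expect_true(all(ss$ss[!interior] == "C"))
})

test_that("select_random_sites enforces matching and separation", {
  st <- fx_mini()$structure
  expect_length(select_random_sites(st, "A:6", 0), 0L)
  sites <- select_random_sites(st, "A:6", 2, min_rel_sasa = 0.10,
                               min_separation = 6, min_total_volume = 0,
                               seed = 3)
  expect_length(sites, 2L)
  ss <- secondary_structure(st)
  key <- paste(ss$chain_id, ss$residue_number)
  site_ss <- ss$ss[key == "A 6"]
  cas <- lapply(sites, function(s) {
    r <- resolve_selector(st, s)
    unlist(r[r$name == "CA", c("x", "y", "z")])
  })
  for (s in sites)
    expect_equal(ss$ss[key == paste(s$chain_id, s$residue_number)], site_ss)
  expect_gte(sqrt(sum((cas[[1]] - cas[[2]])^2)), 6)
  # infeasible request reports the count found
  expect_error(select_random_sites(st, "A:6", 15, min_rel_sasa = 0.10,
                                   min_separation = 6, min_total_volume = 0),
               "eligible")
})

test_that("biased cumulative curve dominates the unbiased curve", {
  # stochastic dominance holds in distribution (the biased Boltzmann
  # weight is monotone in volume); allow finite-sample slack in the tails
  ens <- hinge_ensembles()
  vu <- ensemble_volumes(ens$unbiased)
  vb <- ensemble_volumes(ens$biased)
  grid_v <- sort(unique(c(vu, vb)))
  fu <- vapply(grid_v, function(v) mean(vu >= v), 0)
  fb <- vapply(grid_v, function(v) mean(vb >= v), 0)
  expect_true(all(fb >= fu - 0.05))
  expect_gt(mean(fb - fu), 0)
})
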