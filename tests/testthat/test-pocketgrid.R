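test_that("grid labelling separates protein, surface and solvent", {
  # single carbon at the origin
  st <- atom_pair(40)                      # partner far outside capture
  p <- pocket_params(capture_radius = 6, padding = 4)
  suppressWarnings(g <- build_grid(st, "A:1", p))
  at_point <- function(g, xyz) {
    rel <- round((xyz - g$spec$origin) / g$spec$spacing)
    g$label[1 + rel[1] + g$spec$dims[1] * (rel[2] + g$spec$dims[2] * rel[3])]
  }
  expect_true(at_point(g, c(0, 0, 0)) %in%
                c(GRID_PROTEIN <- 1L, 2L))   # occupied (surface here: r<1 grid)
  expect_identical(at_point(g, c(5, 0, 0)), 0L)  # solvent 5 A away
  # every protein point adjacent to solvent is surface-labelled
  expect_true(any(g$label == 2L))
})

test_that("channel between slabs yields events; wide or convex does not", {
  ch <- fx_channel()$structure
  p <- pocket_params()
  suppressWarnings({
    g <- scan_sss(build_grid(ch, "A:1", p), p)
  })
  # interior gap points (z ~ 0 mid-gap) collect events along the normal
  mid <- which(g$label == 0L & g$events >= 1L)
  expect_gt(length(mid), 0)

  # 20 A apart: the gap-spanning direction can collect no events (span
  # cap 12 A); residual events are sub-grid surface corrugation, which
  # the deep split discards entirely
  wide <- make_fixture(fixture_spec("channel", gap = 20))$structure
  suppressWarnings(gwb <- build_grid(wide, "A:1", p))
  ev_z <- pocketeer:::cpp_scan_sss(gwb$label, gwb$spec$dims,
                                   gwb$spec$spacing,
                                   matrix(c(0L, 0L, 1L), 1), p$max_span)
  expect_true(all(ev_z == 0L))
  expect_equal(suppressWarnings(deep_pocket_volume(wide, "A:1", p)), 0)

  # isolated convex ball: no concavity, no events
  co <- pocketeer:::.coords1d(4.2, 1.2)
  xyz <- as.matrix(expand.grid(x = co, y = co, z = co))
  xyz <- xyz[sqrt(rowSums(xyz^2)) <= 4.2, ]
  ball <- assign_radii(pocketeer:::.new_structure(
    pocketeer:::.lattice_atoms(xyz), 1L, "ball"))
  suppressWarnings(gb <- scan_sss(build_grid(ball, "A:1", p), p))
  expect_true(all(gb$events == 0L))
})

test_that("deep/surface split respects the 2.5 A bulk-distance rule", {
  fl <- fx_flask()$structure
  p <- pocket_params()
  suppressWarnings({
    g <- mark_pockets(scan_sss(build_grid(fl, "A:1", p), p), p)
  })
  expect_gt(sum(g$label == 4L), 0)         # deep interior
  expect_gt(sum(g$label == 3L), 0)         # surface pocket near the mouth
  # every surface-pocket point is within deep_cutoff of a bulk point;
  # every deep point is not (verified exhaustively)
  bulk <- which(g$label == 0L) - 1L
  bxyz <- pocketeer:::.grid_coords(g$spec, bulk)
  near_bulk <- function(lin0) {
    xyz <- pocketeer:::.grid_coords(g$spec, lin0)
    vapply(seq_len(nrow(xyz)), function(i) {
      d2 <- (bxyz[, 1] - xyz[i, 1])^2 + (bxyz[, 2] - xyz[i, 2])^2 +
        (bxyz[, 3] - xyz[i, 3])^2
      # exterior of the box is also bulk
      rel <- (xyz[i, ] - g$spec$origin) / g$spec$spacing
      d_ext <- (min(rel, g$spec$dims - 1 - rel) + 1) * g$spec$spacing
      min(sqrt(min(d2)), d_ext) <= p$deep_cutoff
    }, TRUE)
  }
  expect_true(all(near_bulk(which(g$label == 3L) - 1L)))
  expect_false(any(near_bulk(which(g$label == 4L) - 1L)))
})

test_that("clustering separates cavities and flags target contact", {
  # two flask cavities in one structure, one residue each
  fl <- fx_flask()$structure
  a1 <- fl$atoms; a2 <- fl$atoms
  a2$x <- a2$x + 24
  a2$residue_number <- 2L
  both <- fl
  both$atoms <- rbind(a1, a2)
  both$atoms$serial <- seq_len(nrow(both$atoms))
  p <- pocket_params(capture_radius = 40)
  suppressWarnings(ps <- detect_pockets(both, "A:1", p))
  big <- Filter(function(q) q$deep_volume > 50, ps$pockets)
  expect_length(big, 2L)
  # cavity 1 surrounds residue 1 (target): contact TRUE; distal cavity FALSE
  expect_setequal(vapply(big, `[[`, TRUE, "contacts_target"),
                  c(TRUE, FALSE))
  # pockets pairwise disjoint
  expect_length(intersect(big[[1]]$point_indices, big[[2]]$point_indices), 0L)
})

test_that("deep_pocket_volume: slab is 0, flask matches the oracle", {
  expect_equal(deep_pocket_volume(fx_slab()$structure, "A:1"), 0)
  fl <- fx_flask()$structure
  v <- deep_pocket_volume(fl, "A:1")
  g <- brute_force_labels(fl, "A:1")
  expect_equal(v, sum(g$label == 4L) * 1.0^3)
  expect_gt(v, 0)
})

test_that("empty pocket set is allowed and volume falls back to 0", {
  ball_far <- atom_pair(3)   # two atoms, no concavity
  suppressWarnings(ps <- detect_pockets(ball_far, "A:1",
                                        pocket_params(capture_radius = 8)))
  expect_equal(pocketeer:::.deep_volume_from_set(ps), 0)
})

test_that("volumes are integer multiples of spacing^3 and deep <= total", {
  for (seed in 1:3) {
    st <- make_cloud(seed)
    p <- pocket_params(capture_radius = 12)
    suppressWarnings(ps <- detect_pockets(st, "A:1", p))
    for (q in ps$pockets) {
      expect_true(all(q$deep_point_indices %in% q$point_indices))
      expect_equal(q$deep_volume %% p$spacing^3, 0)
      expect_lte(q$deep_volume, q$total_volume)
    }
  }
})

test_that("deep volume is monotone in deep_cutoff, total in max_span", {
  fl <- fx_flask()$structure
  suppressWarnings({
    vols <- vapply(c(1.5, 2.5, 3.5), function(dc)
      deep_pocket_volume(fl, "A:1", pocket_params(deep_cutoff = dc)), 0)
    expect_true(all(diff(vols) <= 0))
    tots <- vapply(c(6, 12, 18), function(ms)
      total_pocket_volume(fl, "A:1", pocket_params(max_span = ms)), 0)
    expect_true(all(diff(tots) >= 0))
  })
})

test_that("integer-spacing translations leave volumes exactly unchanged", {
  fl <- fx_flask()$structure
  v0 <- deep_pocket_volume(fl, "A:1")
  for (shift in list(c(1, 0, 0), c(0, -2, 0), c(3, 1, -1))) {
    tr <- fl
    tr$atoms$x <- tr$atoms$x + shift[1]
    tr$atoms$y <- tr$atoms$y + shift[2]
    tr$atoms$z <- tr$atoms$z + shift[3]
    expect_identical(deep_pocket_volume(tr, "A:1"), v0)
  }
})

test_that("rigid rotations change the flask deep volume by < 30%", {
  fl <- fx_flask()$structure
  v0 <- deep_pocket_volume(fl, "A:1")
  xyz <- as.matrix(fl$atoms[, c("x", "y", "z")])
  set.seed(42)
  for (i in 1:20) {
    # random rotation via QR of a gaussian matrix
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    rot <- fl
    x2 <- xyz %*% R
    rot$atoms$x <- x2[, 1]; rot$atoms$y <- x2[, 2]; rot$atoms$z <- x2[, 3]
    v <- deep_pocket_volume(rot, "A:1")
    expect_lt(abs(v - v0) / v0, 0.30)
  }
})

test_that("13-direction scan finds at least as many events as 7", {
  fl <- fx_flask()$structure
  suppressWarnings({
    p7 <- pocket_params(directions = 7)
    p13 <- pocket_params(directions = 13)
    g7 <- scan_sss(build_grid(fl, "A:1", p7), p7)
    g13 <- scan_sss(build_grid(fl, "A:1", p13), p13)
  })
  expect_true(all(g13$events >= g7$events))
})

test_that("brute-force oracle refuses oversized grids", {
  st <- fx_flask()$structure
  expect_error(brute_force_labels(st, "A:1", pocket_params(spacing = 0.5)),
               "40")
})
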