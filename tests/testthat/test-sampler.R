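test_that("propose_move perturbs only the drawn torsion's dependents", {
  st <- fx_mini()$structure
  cfg <- mc_config(move_mix = c(sidechain_chi = 0, backbone_phi_psi = 1))
  set.seed(5)
  p <- propose_move(st, cfg)
  moved <- which(p$atoms$x != st$atoms$x | p$atoms$y != st$atoms$y |
                   p$atoms$z != st$atoms$z)
  expect_gt(length(moved), 0)
  expect_lt(length(moved), nrow(st$atoms))
  # untouched atoms are bit-identical
  keep <- setdiff(seq_len(nrow(st$atoms)), moved)
  expect_identical(p$atoms[keep, c("x", "y", "z")],
                   st$atoms[keep, c("x", "y", "z")])
})

test_that("zero move size and chi-less structures give identical proposals", {
  st <- fx_mini()$structure
  cfg0 <- mc_config(max_chi_step = 0, max_bb_step = 0)
  set.seed(1)
  expect_identical(propose_move(st, cfg0)$atoms[, c("x", "y", "z")],
                   st$atoms[, c("x", "y", "z")])
  # polyalanine has no heavy-atom chi: a sidechain-only mix is a no-op
  set.seed(2)
  p <- propose_move(st, mc_config(move_mix = c(sidechain_chi = 1,
                                               backbone_phi_psi = 0)))
  expect_identical(p$atoms, st$atoms)
})

test_that("fixed seed reproduces the proposal stream", {
  st <- fx_mini()$structure
  cfg <- mc_config()
  draw <- function() {
    set.seed(99)
    replicate(5, propose_move(st, cfg)$atoms$x, simplify = "matrix")
  }
  expect_identical(draw(), draw())
})

test_that("run_mc: zero steps returns the start; seeds give determinism", {
  st <- fx_hinge()$structure
  cfg0 <- hinge_mc(3, 0, 4)
  ens <- run_mc(st, cfg0, bias_spec("B:1", "none"))
  expect_length(ens$conformations, 3L)
  for (cf in ens$conformations) {
    expect_identical(cf$structure$atoms[, c("x", "y", "z")],
                     st$atoms[, c("x", "y", "z")])
    expect_true(is.na(cf$acceptance_ratio))
  }
  cfg <- hinge_mc(4, 25, 11)
  e1 <- run_mc(st, cfg, bias_spec("B:1", "moderate"))
  e2 <- run_mc(st, cfg, bias_spec("B:1", "moderate"))
  expect_identical(ensemble_volumes(e1), ensemble_volumes(e2))
  expect_identical(e1$conformations[[2]]$structure$atoms,
                   e2$conformations[[2]]$structure$atoms)
})

test_that("disabled bias equals zero-weight bias trajectory for equal seeds", {
  st <- fx_hinge()$structure
  cfg <- hinge_mc(3, 30, 21)
  off <- run_mc(st, cfg, bias_spec("B:1", "none"))
  zero <- run_mc(st, cfg, bias_spec("B:1", "moderate", weight = 0))
  for (i in 1:3)
    expect_identical(off$conformations[[i]]$structure$atoms,
                     zero$conformations[[i]]$structure$atoms)
})

test_that("acceptance ratios are in (0, 1] on fixture runs", {
  st <- fx_hinge()$structure
  ens <- run_mc(st, hinge_mc(5, 40, 31), bias_spec("B:1", "moderate"))
  acc <- vapply(ens$conformations, `[[`, 0, "acceptance_ratio")
  expect_true(all(acc > 0 & acc <= 1))
})

test_that("stored energies re-evaluate to the same values (rescoring)", {
  st <- fx_hinge()$structure
  ens <- run_mc(st, hinge_mc(4, 30, 41), bias_spec("B:1", "moderate"))
  res <- rescore_ensemble(ens, bias_disabled = TRUE)
  for (i in seq_along(res)) {
    stored <- ens$conformations[[i]]$energy
    expect_equal(res[[i]]$base, stored$base, tolerance = 1e-8)
    expect_identical(res[[i]]$bias, 0)
    # components re-sum to the total bit-exactly
    expect_identical(stored$total, stored$base + stored$bias)
  }
  res2 <- rescore_ensemble(ens, bias_disabled = FALSE)
  expect_equal(res2[[1]]$bias, ens$bias_spec$weight *
                 ens$conformations[[1]]$energy$deep_volume)
  expect_error(rescore_ensemble(list(conformations = list())), "empty")
})

test_that("hinge fixture has exactly two clash-free torsion wells", {
  sc <- hinge_scan()
  free <- sc$clash == 0
  # count maximal clash-free runs over the 1-degree scan
  runs <- rle(free)
  expect_equal(sum(runs$values), 2L)
  # the wells bracket the closed (0) and open (~32 degree) states
  wells <- split(sc$angle[free], cumsum(!free)[free])
  wells <- Filter(length, wells)
  expect_true(any(vapply(wells, function(w) 0 %in% w, TRUE)))
  expect_true(any(vapply(wells, function(w) 30 %in% w, TRUE)))
})

test_that("stronger bias weight monotonically raises open-state occupancy", {
  # analytic check via Boltzmann quadrature at three weights, plus a
  # seeded MC consistency check at the strongest
  p0 <- hinge_boltzmann(0)$p_open
  p1 <- hinge_boltzmann(-0.25)$p_open
  p2 <- hinge_boltzmann(-2.5)$p_open
  expect_true(p0 < p1 && p1 <= p2)
  st <- fx_hinge()$structure
  ens <- run_mc(st, hinge_mc(40, 250, 77), bias_spec("B:1", "strong"))
  mc <- open_fraction(ens)
  se <- sqrt(max(p2 * (1 - p2), 0.25 / 40) / 40)
  expect_lt(abs(mc - p2), 3 * se + 1e-9)
})
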