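# Shared fixture builders, memoised so expensive objects are built once
# per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cache)) assign(key, builder(), envir = .cache)
  get(key, envir = .cache)
}

fx_flask <- function() cached("flask", function()
  make_fixture(fixture_spec("flask")))
fx_slab <- function() cached("slab", function()
  make_fixture(fixture_spec("slab")))
fx_channel <- function(gap = 6) cached(paste0("channel", gap), function()
  make_fixture(fixture_spec("channel", gap = gap)))
fx_hinge <- function() cached("hinge", function()
  make_fixture(fixture_spec("hinge_two_state")))
fx_slab_arm <- function() cached("slab_arm", function()
  make_fixture(fixture_spec("slab", arm = TRUE)))
fx_mini <- function() cached("mini", function()
  make_fixture(fixture_spec("mini_protein")))

# random atom cloud; one residue per atom so any atom can be a target
make_cloud <- function(seed, n = 30, spread = 7) {
  set.seed(seed)
  xyz <- matrix(runif(n * 3, -spread, spread), ncol = 3)
  atoms <- pocketeer:::.lattice_atoms(xyz)
  atoms$residue_number <- seq_len(n)
  assign_radii(pocketeer:::.new_structure(atoms, 1L, paste0("cloud", seed)))
}

# a couple of free-standing atoms (for energy arithmetic tests)
atom_pair <- function(d, elements = c("C", "C")) {
  atoms <- pocketeer:::.lattice_atoms(rbind(c(0, 0, 0), c(d, 0, 0)),
                                      element = elements[1])
  atoms$element <- elements
  atoms$is_hydrophobic <- elements %in% c("C", "S")
  atoms$residue_number <- 1:2
  assign_radii(pocketeer:::.new_structure(atoms, 1L, "pair"))
}

# hinge-experiment settings: kT and move size are sampler design choices
# (documented in the methods vignette); the bias weights and the pocket
# parameters are the method's stated constants.
hinge_mc <- function(n_runs, n_steps, seed) {
  mc_config(n_steps = n_steps, n_runs = n_runs, kT = 6, seed = seed,
            max_chi_step = 60,
            move_mix = c(sidechain_chi = 1, backbone_phi_psi = 0),
            mobile_region = list(selector("B", 1L)))
}

# shared hinge ensembles for the acceptance criteria (built once)
hinge_ensembles <- function() cached("hinge_ens", function() {
  st <- fx_hinge()$structure
  list(unbiased = run_mc(st, hinge_mc(200, 300, 101),
                         bias_spec("B:1", "none")),
       biased = run_mc(st, hinge_mc(200, 300, 202),
                       bias_spec("B:1", "moderate")))
})

# 1-degree torsion scan of the hinge: base energy (with restraint) and
# deep volume; the quadrature oracle for two-state occupancies
hinge_scan <- function() cached("hinge_scan", function() {
  fx <- fx_hinge()
  st <- fx$structure
  tors <- pocketeer:::.torsion_table(st, list(selector("B", 1L)))
  chi <- tors[[which(vapply(tors, function(t) t$type == "chi", TRUE))]]
  ec <- energy_config()
  angles <- seq(-179, 180, by = 1)
  suppressWarnings({
    out <- t(vapply(angles, function(a) {
      s2 <- pocketeer:::.apply_torsion(st, chi, a)
      comp <- pocketeer:::.base_components(s2, ec)
      c(E = comp$clash + comp$contact + ec$k_torsion * a^2,
        clash = comp$clash,
        V = deep_pocket_volume(s2, "B:1"))
    }, c(E = 0, clash = 0, V = 0)))
  })
  data.frame(angle = angles, E = out[, "E"], clash = out[, "clash"],
             V = out[, "V"])
})

# Boltzmann quadrature over the scan: open-state occupancy and mean deep
# volume at a bias weight
hinge_boltzmann <- function(weight, kT = 6, open_above = 18) {
  sc <- hinge_scan()
  w <- exp(-(sc$E + weight * sc$V) / kT)
  w <- w / sum(w)
  list(p_open = sum(w[sc$angle > open_above]), mean_V = sum(w * sc$V))
}

open_fraction <- function(ensemble, open_above = 18) {
  mean(vapply(ensemble$conformations,
              function(cf) cf$torsion_deltas[[1]] > open_above, TRUE))
}

expect_same_labels <- function(structure, target, params = pocket_params()) {
  suppressWarnings({
    g1 <- mark_pockets(scan_sss(build_grid(structure, target, params),
                                params), params)
    g2 <- brute_force_labels(structure, target, params)
  })
  expect_identical(g1$spec$dims, g2$spec$dims)
  expect_identical(g1$label, g2$label)
  expect_identical(g1$events, g2$events)
}
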