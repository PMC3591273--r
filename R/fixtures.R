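# Synthetic-structure fixtures with analytically known geometry.
# Lattice toys (slab / channel / flask / sphere_shell) are carbon-atom
# lattices dense enough (1.2 A spacing vs 1.7 A vdW radius) to be
# watertight to the grid.  All lattice atoms of a rigid body share one
# residue, so the pairwise energy terms (which exclude intra-residue
# pairs) see only the interactions that can change: base-vs-arm for the
# articulated fixtures.  The hinge fixture couples a paddle to a single
# chi-like torsion with exactly two clash-free wells: "closed" (paddle
# flat on the slab; no deep pocket beyond residual corrugation) and
# "open" (paddle tilted onto a docking cradle, roofing a deep wedge
# pocket between paddle and slab).

# symmetric 1-D lattice positions: +-(s/2 + k s) up to half (no point at 0)
.coords1d <- function(half, spacing = 1.2) {
  s <- seq(spacing / 2, half + 1e-9, by = spacing)
  c(rev(-s), s)
}

.b36 <- function(i) {
  digits <- c(0:9, LETTERS)
  vapply(i, function(v) {
    out <- character(3)
    for (p in 3:1) { out[p] <- digits[v %% 36 + 1]; v <- v %/% 36 }
    paste(out, collapse = "")
  }, "")
}

# build an atom data frame from coordinates (single element, one residue)
.lattice_atoms <- function(xyz, chain = "A", resno = 1L, resname = "LAT",
                           element = "C", name_prefix = "C", serial0 = 0L,
                           names = NULL) {
  n <- nrow(xyz)
  if (is.null(names)) names <- paste0(name_prefix, .b36(seq_len(n)))
  data.frame(
    serial = serial0 + seq_len(n), name = names, element = element,
    residue_name = resname, chain_id = chain, residue_number = resno,
    insertion_code = "", alt_loc = "", occupancy = 1,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_het = FALSE, is_h = FALSE, vdw_radius = NA_real_,
    is_hydrophobic = element %in% c("C", "S"),
    stringsAsFactors = FALSE)
}

.fixture_structure <- function(atom_frames, label) {
  atoms <- do.call(rbind, atom_frames)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  assign_radii(.new_structure(atoms, model_id = 1L, source_label = label))
}

#' Synthetic-fixture specification
#'
#' @param kind One of `"slab"`, `"channel"`, `"flask"`, `"sphere_shell"`,
#'   `"hinge_two_state"`, `"mini_protein"`.
#' @param ... Kind-specific geometry overrides (Angstrom):
#'   slab: `half_x`, `half_y`, `n_layers`, `arm` (logical: mount the hinge
#'   paddle on the flat surface);
#'   channel: `gap` (van der Waals surface separation), `half_x`, `half_y`;
#'   flask: `a` (interior cube side), `mouth` (mouth width);
#'   sphere_shell: `radius`, `thickness`;
#'   mini_protein: `n_res` (per helix), `separation`.
#' @param atom_element Element for lattice atoms (default `"C"`).
#' @param lattice_spacing Lattice spacing, Angstrom (default 1.2; must stay
#'   below twice the element's vdW radius over sqrt 3 for watertight walls).
#' @param seed Integer seed (fixtures are deterministic; kept for API
#'   stability).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("slab", "channel", "flask", "sphere_shell",
                                  "hinge_two_state", "mini_protein"),
                         ..., atom_element = "C", lattice_spacing = 1.2,
                         seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, geometry = list(...),
                 atom_element = atom_element,
                 lattice_spacing = lattice_spacing, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @return List with `structure` (a radii-assigned `pocket_structure`) and
#'   `truth` (analytic cavity volume where defined, the target selector,
#'   and for the hinge the two torsion-well descriptions).
#' @export
make_fixture <- function(spec) {
  g <- spec$geometry
  ls <- spec$lattice_spacing
  el <- spec$atom_element
  switch(spec$kind,
         slab = .fx_slab(g, ls, el),
         channel = .fx_channel(g, ls, el),
         flask = .fx_flask(g, ls, el),
         sphere_shell = .fx_sphere(g, ls, el),
         hinge_two_state = .fx_hinge(g, ls, el, with_dock = TRUE),
         mini_protein = .fx_miniprot(g))
}

.fx_slab <- function(g, ls, el) {
  half_x <- g$half_x %||% 7.8
  half_y <- g$half_y %||% 7.8
  n_layers <- g$n_layers %||% 4L
  arm <- isTRUE(g$arm)
  if (arm) return(.fx_hinge(g, ls, el, with_dock = FALSE))
  xyz <- as.matrix(expand.grid(x = .coords1d(half_x, ls),
                               y = .coords1d(half_y, ls),
                               z = -ls / 2 - ls * (0:(n_layers - 1L))))
  st <- .fixture_structure(list(.lattice_atoms(xyz, element = el)),
                           "fixture:slab")
  list(structure = st,
       truth = list(analytic_cavity_volume = 0,
                    target = selector("A", 1L)))
}

.fx_channel <- function(g, ls, el) {
  gap <- g$gap %||% 6
  half_x <- g$half_x %||% 9.0
  half_y <- g$half_y %||% 9.0
  r <- .radius_lookup(el)
  z0 <- gap / 2 + r   # facing atom-centre planes so vdW surfaces are `gap` apart
  zs <- z0 + ls * (0:2)
  xyz <- rbind(
    as.matrix(expand.grid(x = .coords1d(half_x, ls),
                          y = .coords1d(half_y, ls), z = zs)),
    as.matrix(expand.grid(x = .coords1d(half_x, ls),
                          y = .coords1d(half_y, ls), z = -zs)))
  st <- .fixture_structure(list(.lattice_atoms(xyz, element = el)),
                           "fixture:channel")
  list(structure = st,
       truth = list(analytic_cavity_volume = NA_real_, gap = gap,
                    target = selector("A", 1L)))
}

.fx_flask <- function(g, ls, el) {
  a <- g$a %||% 5
  mouth <- g$mouth %||% 2
  if (mouth >= a) stop("flask mouth must be narrower than the cavity")
  r <- .radius_lookup(el)
  wall_in <- a / 2 + r                  # innermost wall-atom centre plane
  half <- wall_in + 2 * ls              # two extra wall layers
  co <- .coords1d(half, ls)
  xyz <- as.matrix(expand.grid(x = co, y = co, z = co))
  maxabs <- pmax(abs(xyz[, 1]), abs(xyz[, 2]), abs(xyz[, 3]))
  keep <- maxabs >= wall_in - 1e-9      # carve the cubic cavity
  # carve the mouth channel through the +z wall
  mouth_block <- abs(xyz[, 1]) < mouth / 2 + r &
    abs(xyz[, 2]) < mouth / 2 + r & xyz[, 3] > a / 2
  xyz <- xyz[keep & !mouth_block, , drop = FALSE]
  st <- .fixture_structure(list(.lattice_atoms(xyz, element = el)),
                           "fixture:flask")
  list(structure = st,
       truth = list(analytic_cavity_volume = a^3, mouth = mouth,
                    target = selector("A", 1L)))
}

.fx_sphere <- function(g, ls, el) {
  radius <- g$radius %||% 8
  thickness <- g$thickness %||% 3.5
  r <- .radius_lookup(el)
  co <- .coords1d(radius, ls)
  xyz <- as.matrix(expand.grid(x = co, y = co, z = co))
  nr <- sqrt(rowSums(xyz^2))
  xyz <- xyz[nr <= radius & nr >= radius - thickness, , drop = FALSE]
  st <- .fixture_structure(list(.lattice_atoms(xyz, element = el)),
                           "fixture:sphere_shell")
  list(structure = st,
       truth = list(
         analytic_cavity_volume = 4 / 3 * pi * (radius - thickness - r)^3,
         target = selector("A", 1L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Articulated paddle fixture.  with_dock = TRUE gives the two-state
# hinge: a paddle plate lying flat on a slab (closed; no pocket) can tilt
# about a single chi-like torsion into a docking cradle (open), roofing a
# deep wedge pocket between plate and slab at little net energy cost.
# with_dock = FALSE mounts the same paddle on the bare slab: the
# "pocketless" site, where the same wedge volume can only be bought by
# losing the plate-slab contacts and paying the torsion restraint.
.fx_hinge <- function(g, ls, el, with_dock = TRUE) {
  half_x <- 7.8; half_y <- 7.8
  open_angle <- g$open_angle %||% 32
  plate_z <- g$plate_z %||% 2.6
  slab_z <- -(ls / 2) - ls * (0:3)                 # -0.6 .. -4.2
  base <- as.matrix(expand.grid(x = .coords1d(half_x, ls),
                                y = .coords1d(half_y, ls), z = slab_z))
  # back wall at y = -9 blocks the flipped-over (|angle| ~ 180) state
  back <- as.matrix(expand.grid(x = .coords1d(half_x, ls), y = -9.6,
                                z = c(0.6, 1.8, 3.0, 4.2)))
  base <- rbind(base, back)
  if (with_dock) {
    # latch row: grazes the swinging plate mid-arc, separating the two
    # wells with a narrow (< 30 degree) clash band
    latch <- as.matrix(expand.grid(x = seq(-2.8, 2.8, by = 1.4),
                                   y = g$latch_y %||% 6.20,
                                   z = g$latch_z %||% 6.71))
    # cradle fingers: three sparse rows parallel to the open-plate plane,
    # offset just outside clash range; they reward the open state with
    # contacts comparable to the closed plate-slab interface.  Finger
    # spacing (4.2 A) leaves sky-open corridors so the cradle itself
    # roofs no deep pocket in the closed state.
    oa <- open_angle * pi / 180
    lys <- seq(g$cradle_from %||% 3.2, g$cradle_to %||% 11.5,
               by = g$cradle_step %||% 0.30)
    cradle <- do.call(rbind, lapply(g$cradle_offsets %||% c(3.2, 4.0, 4.8),
                                    function(off) {
      finger_y <- -6.2 + lys * cos(oa) - (off + plate_z - 2.2) * sin(oa)
      finger_z <- 2.2 + lys * sin(oa) + (off + plate_z - 2.2) * cos(oa)
      do.call(rbind, lapply(g$finger_x %||% c(-4.9, 0, 4.9), function(fx)
        cbind(fx, finger_y, finger_z)))
    }))
    base <- rbind(base, latch, cradle)
  }

  # arm: pivot triad (N, CA, CB; chi axis CA->CB along +x at y=-6.2,
  # z=2.2) plus the paddle plate
  plate <- as.matrix(expand.grid(x = seq(-2.8, 2.8, by = 1.4),
                                 y = seq(-6.2, 5.0, by = 1.4), z = plate_z))
  triad <- rbind(N = c(0, -6.2, 3.7), CA = c(0, -6.2, 2.2),
                 CB = c(1.2, -6.2, 2.2))
  arm_xyz <- rbind(triad, plate)
  arm_names <- c("N", "CA", "CB", paste0("P", .b36(seq_len(nrow(plate)))))

  base_at <- .lattice_atoms(base, chain = "A", resno = 1L, resname = "BAS",
                            element = el, name_prefix = "B")
  arm_at <- .lattice_atoms(arm_xyz, chain = "B", resno = 1L, resname = "ARM",
                           element = el, names = arm_names)
  st <- .fixture_structure(list(base_at, arm_at),
                           if (with_dock) "fixture:hinge_two_state"
                           else "fixture:slab_arm")
  list(structure = st,
       truth = list(
         analytic_cavity_volume = NA_real_,
         target = selector("B", 1L),
         arm = selector("B", 1L),
         closed_angle = 0,
         open_angle = if (with_dock) open_angle else NA_real_))
}

# --- polyalanine mini-protein -------------------------------------------

# NeRF atom placement: position d bonded to c with given internal coords
.place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180   # sign matches the .dihedral convention
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  n <- c((b - a)[2] * bc[3] - (b - a)[3] * bc[2],
         (b - a)[3] * bc[1] - (b - a)[1] * bc[3],
         (b - a)[1] * bc[2] - (b - a)[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal-geometry polyalanine chain from a phi/psi list
.build_polyala <- function(phipsi, chain = "A", serial0 = 0L) {
  n <- nrow(phipsi)
  atoms <- list()
  # seed residue 1 backbone
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- .place_atom(c(-1, 1, 0), N, CA, 1.525, 111.2, phipsi$phi[1] %||% -57)
  for (i in seq_len(n)) {
    O <- .place_atom(N, CA, C, 1.231, 120.5,
                     (if (i < n) phipsi$psi[i] else 0) - 180)
    CB <- .place_atom(C, N, CA, 1.530, 110.4, 122.5)
    res <- data.frame(
      serial = 0L, name = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
      residue_name = "ALA", chain_id = chain, residue_number = i,
      insertion_code = "", alt_loc = "", occupancy = 1,
      x = c(N[1], CA[1], C[1], O[1], CB[1]),
      y = c(N[2], CA[2], C[2], O[2], CB[2]),
      z = c(N[3], CA[3], C[3], O[3], CB[3]),
      is_het = FALSE, is_h = FALSE, vdw_radius = NA_real_,
      is_hydrophobic = c(FALSE, TRUE, TRUE, FALSE, TRUE),
      stringsAsFactors = FALSE)
    atoms[[i]] <- res
    if (i < n) {
      Nn <- .place_atom(N, CA, C, 1.329, 116.2, phipsi$psi[i])
      CAn <- .place_atom(CA, C, Nn, 1.458, 121.7, 180)
      Cn <- .place_atom(C, Nn, CAn, 1.525, 111.2, phipsi$phi[i + 1])
      N <- Nn; CA <- CAn; C <- Cn
    }
  }
  out <- do.call(rbind, atoms)
  out$serial <- serial0 + seq_len(nrow(out))
  out
}

# CB atoms placed relative to N/CA/C; .place_atom above uses (C, N, CA)

.fx_miniprot <- function(g) {
  n_res <- g$n_res %||% 10L
  separation <- g$separation %||% 9.5
  phipsi <- data.frame(phi = rep(-57, n_res), psi = rep(-47, n_res))
  ha <- .build_polyala(phipsi, chain = "A")
  hb <- .build_polyala(phipsi, chain = "B")
  # antiparallel second helix: rotate 180 deg about x, offset in y; then
  # push apart until the closest inter-chain approach is a packing
  # distance (deterministic)
  hb$y <- -hb$y + separation
  hb$z <- -hb$z
  for (pass in 1:5) {
    dmin <- min(vapply(seq_len(nrow(hb)), function(j)
      min(sqrt((ha$x - hb$x[j])^2 + (ha$y - hb$y[j])^2 +
                 (ha$z - hb$z[j])^2)), 0))
    if (dmin >= 4.6) break
    hb$y <- hb$y + (4.6 - dmin)
  }
  hb$serial <- max(ha$serial) + seq_len(nrow(hb))
  atoms <- rbind(ha, hb)
  st <- .fixture_structure(list(atoms), "fixture:mini_protein")
  list(structure = st,
       truth = list(analytic_cavity_volume = NA_real_,
                    target = selector("A", as.integer(ceiling(n_res / 2)))))
}

#' Write the canonical fixture suite to a directory
#'
#' Writes one PDB per fixture kind plus a JSON manifest of the analytic
#' truths.  Output is deterministic (byte-identical across runs).
#'
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_fixture_suite <- function(directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  kinds <- c("slab", "channel", "flask", "sphere_shell", "hinge_two_state",
             "mini_protein")
  manifest <- list()
  for (k in kinds) {
    fx <- make_fixture(fixture_spec(k))
    path <- file.path(directory, paste0(k, ".pdb"))
    write_pdb(fx$structure, path)
    manifest[[k]] <- list(
      file = basename(path),
      n_atoms = n_atoms(fx$structure),
      analytic_cavity_volume = fx$truth$analytic_cavity_volume,
      target = format(fx$truth$target))
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
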