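# Ensemble analytics: interface derivation from a bound complex, minimum
# interface RMSD against a reference set, Shrake-Rupley SASA and the
# hydrophobic fraction of a pocket lining, cumulative volume curves, and
# matched random surface-site selection.

#' Derive an interface definition from an inhibitor-bound complex
#'
#' The interface is the set of protein residues with any heavy atom within
#' `contact_cutoff` of any heavy atom of the (single) bound HETATM ligand.
#'
#' @param bound_structure A `pocket_structure` still containing exactly one
#'   non-water HETATM ligand.
#' @param contact_cutoff Contact distance, Angstrom (default 5.0).
#' @param atom_scope `"heavy"` (all heavy atoms) or `"backbone"` (N, CA,
#'   C, O) for later RMSD evaluation.
#' @return Object of class `interface_def`: list of residue selectors plus
#'   the derivation rule.
#' @export
derive_interface <- function(bound_structure, contact_cutoff = 5.0,
                             atom_scope = c("heavy", "backbone")) {
  atom_scope <- match.arg(atom_scope)
  a <- bound_structure$atoms
  lig <- a[a$is_het & !a$is_h, , drop = FALSE]
  if (nrow(lig) == 0L) stop("no HETATM ligand in bound structure")
  lkey <- unique(paste(lig$chain_id, lig$residue_number, lig$residue_name))
  if (length(lkey) > 1L)
    stop("expected exactly one ligand, found: ", paste(lkey, collapse = "; "))
  prot <- a[!a$is_het & !a$is_h, , drop = FALSE]
  if (contact_cutoff <= 0) stop("contact_cutoff must be positive")

  hit <- logical(nrow(prot))
  for (i in seq_len(nrow(lig))) {
    d2 <- (prot$x - lig$x[i])^2 + (prot$y - lig$y[i])^2 +
      (prot$z - lig$z[i])^2
    hit <- hit | d2 <= contact_cutoff^2
  }
  if (!any(hit)) stop("ligand makes no protein contacts within ",
                      contact_cutoff, " A")
  res <- unique(prot[hit, c("chain_id", "residue_number", "insertion_code")])
  sels <- lapply(seq_len(nrow(res)), function(i)
    selector(res$chain_id[i], res$residue_number[i], res$insertion_code[i]))
  structure(list(residues = sels, atom_scope = atom_scope,
                 derivation = sprintf(
                   "ligand heavy-atom contact rule, cutoff %.1f A (ligand %s)",
                   contact_cutoff, lkey)),
            class = "interface_def")
}

#' @export
print.interface_def <- function(x, ...) {
  cat(sprintf("<interface_def> %d residue(s), scope %s\n  %s\n",
              length(x$residues), x$atom_scope, x$derivation))
  invisible(x)
}

# coordinates of named atoms for a residue list; errors on mismatch
.interface_coords <- function(structure, interface) {
  scope_names <- if (interface$atom_scope == "backbone")
    c("N", "CA", "C", "O") else NULL
  out <- list()
  for (sel in interface$residues) {
    res <- resolve_selector(structure, sel)
    if (!is.null(scope_names))
      res <- res[res$name %in% scope_names, , drop = FALSE]
    ord <- order(res$name)
    out[[format(sel)]] <- data.frame(atom = paste0(format(sel), "/",
                                                   res$name[ord]),
                                     x = res$x[ord], y = res$y[ord],
                                     z = res$z[ord],
                                     stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# optimal least-squares superposition (Kabsch, via SVD); returns P aligned
# onto Q. P, Q: n x 3 with matched rows.
.kabsch_align <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, cp = cp, cq = cq,
       apply = function(X) sweep(sweep(X, 2L, cp) %*% t(R), 2L, cq, `+`))
}

# CA atoms shared by two structures, keyed by chain/resnum/icode
.shared_ca <- function(s1, s2) {
  ca <- function(s) {
    a <- s$atoms
    a <- a[a$name == "CA" & !a$is_h & !a$is_het, , drop = FALSE]
    key <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = "\r")
    a <- a[!duplicated(key), , drop = FALSE]
    rownames(a) <- paste(a$chain_id, a$residue_number, a$insertion_code,
                         sep = "\r")
    a
  }
  a1 <- ca(s1); a2 <- ca(s2)
  shared <- intersect(rownames(a1), rownames(a2))
  if (length(shared) < 3L) stop("fewer than 3 shared CA atoms for superposition")
  list(P = as.matrix(a1[shared, c("x", "y", "z")]),
       Q = as.matrix(a2[shared, c("x", "y", "z")]))
}

#' Minimum interface RMSD against a reference set
#'
#' For each reference: superpose the conformation onto the reference by
#' least squares over shared CA atoms (all shared CAs for
#' `superposition = "global"`, interface CAs only for `"local"`), then
#' compute the RMSD over the interface atoms in the interface's atom
#' scope.  Returns the minimum across references.
#'
#' @param conformation A `pocket_structure`.
#' @param reference_set A list of `pocket_structure` (inhibitor-bound,
#'   ligand stripped) or a single structure.
#' @param interface An `interface_def`.
#' @param superposition `"global"` (default) or `"local"`.
#' @return Minimum iRMSD in Angstrom, with the per-reference values in
#'   `attr(, "per_reference")`.
#' @export
min_irmsd <- function(conformation, reference_set, interface,
                      superposition = c("global", "local")) {
  superposition <- match.arg(superposition)
  if (inherits(reference_set, "pocket_structure"))
    reference_set <- list(reference_set)
  stopifnot(length(reference_set) >= 1L)
  vals <- vapply(reference_set, function(ref) {
    ic <- .interface_coords(conformation, interface)
    ir <- .interface_coords(ref, interface)
    if (!identical(ic$atom, ir$atom)) {
      bad <- union(setdiff(ic$atom, ir$atom), setdiff(ir$atom, ic$atom))
      stop("interface atom mismatch between conformation and reference: ",
           paste(bad, collapse = ", "))
    }
    if (superposition == "global") {
      sc <- .shared_ca(conformation, ref)
      fit <- .kabsch_align(sc$P, sc$Q)
    } else {
      iface_ca <- interface
      iface_ca$atom_scope <- "backbone"
      pc <- .interface_coords(conformation, iface_ca)
      pr <- .interface_coords(ref, iface_ca)
      keep <- grepl("/CA$", pc$atom)
      fit <- .kabsch_align(as.matrix(pc[keep, c("x", "y", "z")]),
                           as.matrix(pr[keep, c("x", "y", "z")]))
    }
    moved <- fit$apply(as.matrix(ic[, c("x", "y", "z")]))
    sqrt(mean(rowSums((moved - as.matrix(ir[, c("x", "y", "z")]))^2)))
  }, 0)
  out <- min(vals)
  attr(out, "per_reference") <- vals
  out
}

# deterministic near-uniform sphere points (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-sampling SASA over the heavy atoms of a structure.
#'
#' @param structure A `pocket_structure` with radii assigned.
#' @param probe_radius Solvent probe radius, Angstrom.
#' @param n_points Sphere sample points per atom (>= 960 recommended).
#' @return Numeric vector of per-heavy-atom areas (Angstrom^2), in the
#'   order of the structure's heavy atoms.
#' @export
shrake_rupley_sasa <- function(structure, probe_radius = 1.4,
                               n_points = 960L) {
  a <- structure$atoms[!structure$atoms$is_h, , drop = FALSE]
  if (anyNA(a$vdw_radius)) stop("radii not assigned")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rr <- a$vdw_radius + probe_radius
  sp <- .sphere_points(n_points)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * rr[i], 2L, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 <= (rr + rr[i])^2 & seq_len(n) != i)
    for (j in nb) {
      if (!any(free)) break
      dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & dd > rr[j]^2
    }
    out[i] <- 4 * pi * rr[i]^2 * sum(free) / n_points
  }
  out
}

#' Hydrophobic SASA fraction of a pocket lining
#'
#' Computes Shrake-Rupley SASA over the whole structure and reports the
#' percentage of the pocket-lining area contributed by hydrophobic
#' (carbon / sulfur) atoms.
#'
#' @param structure A `pocket_structure` with radii assigned.
#' @param pocket One pocket from a `pocket_set` (must have lining atoms).
#' @param probe_radius,n_points Passed to [shrake_rupley_sasa()].
#' @return Object of class `sasa_result` with `per_atom_area`,
#'   `hydrophobic_area`, `total_area`, `pct_hsasa`.
#' @export
pocket_hsasa <- function(structure, pocket, probe_radius = 1.4,
                         n_points = 960L) {
  if (length(pocket$lining_rows) == 0L) stop("pocket has no lining atoms")
  area <- shrake_rupley_sasa(structure, probe_radius, n_points)
  heavy <- structure$atoms[!structure$atoms$is_h, , drop = FALSE]
  lin <- pocket$lining_rows
  tot <- sum(area[lin])
  if (tot <= 0) stop("pocket lining has zero exposed area; %hSASA undefined")
  hyd <- sum(area[lin][heavy$is_hydrophobic[lin]])
  structure(list(per_atom_area = area, hydrophobic_area = hyd,
                 total_area = tot, pct_hsasa = 100 * hyd / tot),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> lining %.1f A^2, hydrophobic %.1f A^2 (%.1f%%)\n",
              x$total_area, x$hydrophobic_area, x$pct_hsasa))
  invisible(x)
}

#' Cumulative volume curve
#'
#' Fraction of ensemble members whose pocket volume is at least `v`, for
#' each distinct observed volume (plus 0).  Monotonically non-increasing;
#' the fraction at 0 is 1.
#'
#' @param volumes Numeric vector of per-conformation volumes.
#' @return Data frame with columns `volume` and `fraction`.
#' @export
cumulative_volume_curve <- function(volumes) {
  stopifnot(length(volumes) >= 1L, all(volumes >= 0))
  vs <- sort(unique(c(0, volumes)))
  frac <- vapply(vs, function(v) mean(volumes >= v), 0)
  data.frame(volume = vs, fraction = frac)
}

# secondary-structure class from backbone dihedrals (no DSSP dependency):
# H (helix): phi in (-120, -30) and psi in (-80, 40)
# E (strand): phi in (-180, -45) and (psi > 90 or psi < -150)
# C (coil): everything else, including undefined dihedrals
.ss_class <- function(phi, psi) {
  ifelse(is.na(phi) | is.na(psi), "C",
  ifelse(phi > -120 & phi < -30 & psi > -80 & psi < 40, "H",
  ifelse(phi > -180 & phi < -45 & (psi > 90 | psi < -150), "E", "C")))
}

#' Secondary-structure classes of all residues
#' @param structure A `pocket_structure` with backbone atoms.
#' @return Data frame: residue identity plus class `H`/`E`/`C`.
#' @export
secondary_structure <- function(structure) {
  bd <- backbone_dihedrals(structure)
  bd$ss <- .ss_class(bd$phi, bd$psi)
  bd
}

# relative sidechain SASA per residue (observed / reference maximum);
# reference values: theoretical maximum sidechain SASA (Tien et al. 2013,
# PLoS ONE 8:e80635), GLY given its backbone-only maximum
.max_sidechain_sasa <- c(
  ALA = 67, ARG = 196, ASN = 113, ASP = 106, CYS = 104, GLN = 144,
  GLU = 138, GLY = 25, HIS = 151, ILE = 140, LEU = 137, LYS = 167,
  MET = 160, PHE = 175, PRO = 105, SER = 80, THR = 102, TRP = 217,
  TYR = 187, VAL = 117)

#' Select random surface sites matched to an interaction site
#'
#' Seeded random selection of surface residues that (i) are solvent
#' exposed (relative sidechain SASA above `min_rel_sasa`), (ii) share the
#' interaction-site residue's secondary-structure class, (iii) lie
#' pairwise and from the interaction site at least `min_separation` apart
#' (CA-CA), and (iv) have an adjacent pocket of total volume above
#' `min_total_volume` by this package's own detector (the stand-in for an
#' external probe-based site-volume gate).
#'
#' @param structure A `pocket_structure` with radii assigned.
#' @param interaction_site A `residue_selector` or string.
#' @param n_sites Number of sites requested.
#' @param params [pocket_params()] for the gating volume.
#' @param min_rel_sasa Relative sidechain SASA threshold (default 0.25).
#' @param min_separation Minimum CA-CA distance, Angstrom (default 12).
#' @param min_total_volume Total-pocket-volume gate, cubic Angstrom
#'   (default 100).
#' @param seed Integer seed.
#' @return List of `residue_selector` (length `n_sites`; may be empty for
#'   `n_sites = 0`).
#' @export
select_random_sites <- function(structure, interaction_site, n_sites,
                                params = pocket_params(),
                                min_rel_sasa = 0.25, min_separation = 12,
                                min_total_volume = 100, seed = 1L) {
  if (n_sites == 0L) return(list())
  if (is.character(interaction_site))
    interaction_site <- parse_selector(interaction_site)
  a <- structure$atoms[!structure$atoms$is_h & !structure$atoms$is_het, ,
                       drop = FALSE]
  area <- shrake_rupley_sasa(structure)
  heavy <- structure$atoms[!structure$atoms$is_h, , drop = FALSE]
  ss <- secondary_structure(structure)
  key <- paste(ss$chain_id, ss$residue_number, ss$insertion_code, sep = "\r")

  site_key <- paste(interaction_site$chain_id,
                    interaction_site$residue_number,
                    interaction_site$insertion_code, sep = "\r")
  site_ss <- ss$ss[match(site_key, key)]
  if (is.na(site_ss)) stop("interaction site not found in structure")

  ca_of <- function(k) {
    hit <- which(paste(heavy$chain_id, heavy$residue_number,
                       heavy$insertion_code, sep = "\r") == k &
                   heavy$name == "CA")
    if (length(hit) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(heavy$x[hit[1]], heavy$y[hit[1]], heavy$z[hit[1]])
  }
  site_ca <- ca_of(site_key)

  # per-residue relative sidechain SASA
  rel_sasa <- vapply(seq_along(key), function(ri) {
    rows <- which(paste(heavy$chain_id, heavy$residue_number,
                        heavy$insertion_code, sep = "\r") == key[ri])
    side <- rows[!(heavy$name[rows] %in% c("N", "CA", "C", "O"))]
    resname <- heavy$residue_name[rows[1]]
    ref <- .max_sidechain_sasa[[resname]]
    if (is.null(ref) || is.na(ref)) ref <- 100
    if (length(side) == 0L) side <- rows   # GLY: use backbone exposure
    sum(area[side]) / ref
  }, 0)

  eligible <- which(key != site_key & ss$ss == site_ss &
                      rel_sasa > min_rel_sasa)
  # distance from interaction site
  if (!anyNA(site_ca)) {
    far <- vapply(eligible, function(ri) {
      ca <- ca_of(key[ri])
      if (anyNA(ca)) return(FALSE)
      sqrt(sum((ca - site_ca)^2)) >= min_separation
    }, TRUE)
    eligible <- eligible[far]
  }

  set.seed(seed)
  eligible <- eligible[sample.int(length(eligible))]
  chosen <- list()
  chosen_ca <- list()
  for (ri in eligible) {
    if (length(chosen) == n_sites) break
    ca <- ca_of(key[ri])
    if (anyNA(ca)) next
    if (length(chosen_ca) > 0L &&
        any(vapply(chosen_ca, function(c2)
          sqrt(sum((ca - c2)^2)) < min_separation, TRUE))) next
    sel <- selector(ss$chain_id[ri], ss$residue_number[ri],
                    ss$insertion_code[ri])
    tv <- total_pocket_volume(structure, sel, params)
    if (tv <= min_total_volume) next
    chosen[[length(chosen) + 1L]] <- sel
    chosen_ca[[length(chosen_ca) + 1L]] <- ca
  }
  if (length(chosen) < n_sites)
    stop("only ", length(chosen), " eligible random site(s) found, ",
         n_sites, " requested")
  chosen
}
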