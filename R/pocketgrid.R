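# Grid label codes (integer, shared with the C++ kernels)
GRID_SOLVENT <- 0L
GRID_PROTEIN <- 1L
GRID_SURFACE <- 2L
GRID_SURFACE_POCKET <- 3L
GRID_DEEP_POCKET <- 4L

#' Pocket-detection parameters
#'
#' Defaults follow LIGSITE-family precedent where the method itself is
#' silent: 1 Angstrom grid spacing, the 7-direction scan set (3 axes + 4
#' body diagonals; `directions = 13` adds the 6 face diagonals), and a
#' minimum of 2 scan-line events per pocket point as the anti-artifact
#' gate.  The 12 Angstrom span cap and the 2.5 Angstrom deep/surface split
#' are the method's stated constants.
#'
#' @param spacing Grid spacing, Angstrom.
#' @param max_span Maximum Surface-Solvent-Surface flank-to-flank length,
#'   Angstrom.
#' @param deep_cutoff Pocket points within this distance of bulk solvent
#'   are "surface pocket", the rest "deep", Angstrom.
#' @param min_events Minimum number of scan-line events for a solvent point
#'   to become a pocket candidate.
#' @param connectivity Neighbourhood for pocket clustering: 6 or 26.
#' @param directions Scan-direction set: 7 or 13.
#' @param contact_radius Pocket-to-target-atom contact distance, Angstrom.
#' @param capture_radius Protein atoms within this distance of the target
#'   centroid define the grid box, Angstrom.
#' @param padding Box padding beyond the captured atoms, Angstrom.
#' @return Object of class `pocket_params`.
#' @export
pocket_params <- function(spacing = 1.0, max_span = 12.0, deep_cutoff = 2.5,
                          min_events = 2L, connectivity = 26L,
                          directions = 7L, contact_radius = 4.0,
                          capture_radius = 18.0, padding = 4.0) {
  stopifnot(spacing > 0, max_span > 0, deep_cutoff > 0, min_events >= 1,
            contact_radius > 0, capture_radius > 0, padding >= 0,
            connectivity %in% c(6L, 26L), directions %in% c(7L, 13L),
            max_span >= 2 * spacing)
  structure(list(spacing = spacing, max_span = max_span,
                 deep_cutoff = deep_cutoff, min_events = as.integer(min_events),
                 connectivity = as.integer(connectivity),
                 directions = as.integer(directions),
                 contact_radius = contact_radius,
                 capture_radius = capture_radius, padding = padding),
            class = "pocket_params")
}

# scan-direction integer step sets
.scan_directions <- function(n) {
  axes <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  body <- rbind(c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(-1L, 1L, 1L))
  face <- rbind(c(1L, 1L, 0L), c(1L, -1L, 0L), c(1L, 0L, 1L),
                c(1L, 0L, -1L), c(0L, 1L, 1L), c(0L, 1L, -1L))
  if (n == 7L) rbind(axes, body) else rbind(axes, body, face)
}

.heavy_protein <- function(structure) {
  a <- structure$atoms
  a <- a[!a$is_h & !a$is_het, , drop = FALSE]
  if (nrow(a) == 0L) stop("no heavy polymer atoms in structure")
  if (anyNA(a$vdw_radius))
    stop("radii not assigned; call assign_radii() first")
  a
}

# Axis-aligned cube centred on the target-residue heavy-atom centroid,
# covering every captured atom plus padding, snapped to whole grid cells so
# that translating all atoms by integer multiples of the spacing translates
# the grid identically (exact volume invariance).
.grid_spec <- function(structure, target, params) {
  a <- .heavy_protein(structure)
  tgt <- resolve_selector(structure, target)
  cen <- colMeans(tgt[, c("x", "y", "z")])
  d2 <- (a$x - cen[1])^2 + (a$y - cen[2])^2 + (a$z - cen[3])^2
  cap <- a[d2 <= params$capture_radius^2, , drop = FALSE]
  if (nrow(cap) == 0L) cap <- tgt
  half <- max(abs(cap$x - cen[1]), abs(cap$y - cen[2]), abs(cap$z - cen[3])) +
    params$padding
  h <- ceiling(half / params$spacing)
  dims <- rep(2L * as.integer(h) + 1L, 3L)
  origin <- as.numeric(cen) - h * params$spacing
  list(origin = origin, spacing = params$spacing, dims = dims,
       centroid = as.numeric(cen),
       extent_rule = sprintf(
         "cube on target centroid; capture %.1f A + %.1f A padding",
         params$capture_radius, params$padding))
}

.new_grid <- function(spec, label, events, params) {
  structure(list(spec = spec, label = label, events = events,
                 params = params),
            class = "labeled_grid")
}

#' @export
print.labeled_grid <- function(x, ...) {
  tab <- table(factor(x$label, levels = 0:4,
                      labels = c("SOLVENT", "PROTEIN", "SURFACE",
                                 "SURFACE_POCKET", "DEEP_POCKET")))
  cat(sprintf("<labeled_grid> %d x %d x %d @ %.2f A\n",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3], x$spec$spacing))
  print(tab)
  invisible(x)
}

# grid point coordinates for 0-based linear indices
.grid_coords <- function(spec, lin0) {
  nx <- spec$dims[1]; ny <- spec$dims[2]
  i <- lin0 %% nx
  j <- (lin0 %/% nx) %% ny
  k <- lin0 %/% (nx * ny)
  cbind(spec$origin[1] + i * spec$spacing,
        spec$origin[2] + j * spec$spacing,
        spec$origin[3] + k * spec$spacing)
}

#' Build and label the detection grid
#'
#' Labels every grid point PROTEIN (within the van der Waals radius of a
#' heavy atom), SOLVENT, or SURFACE (a protein point with a solvent-class
#' 26-neighbour; points beyond the box count as solvent).  A warning of
#' class `pocketeer_target_buried` is raised when no surface point lies
#' within `contact_radius` of the target's atoms.
#'
#' @param structure A `pocket_structure` with radii assigned.
#' @param target A `residue_selector` or "CHAIN:RESNUM" string.
#' @param params A [pocket_params()] object.
#' @return A `labeled_grid`.
#' @export
build_grid <- function(structure, target, params = pocket_params()) {
  if (is.character(target)) target <- parse_selector(target)
  spec <- .grid_spec(structure, target, params)
  a <- .heavy_protein(structure)
  lab <- cpp_label_grid(as.matrix(a[, c("x", "y", "z")]), a$vdw_radius,
                        spec$origin, spec$spacing, spec$dims)
  g <- .new_grid(spec, lab, integer(length(lab)), params)

  tgt <- resolve_selector(structure, target)
  surf0 <- which(lab == GRID_SURFACE) - 1L
  buried <- TRUE
  if (length(surf0) > 0L) {
    d2 <- cpp_min_dist2_to_atoms(surf0, spec$origin, spec$spacing, spec$dims,
                                 as.matrix(tgt[, c("x", "y", "z")]))
    buried <- !any(d2 <= params$contact_radius^2)
  }
  if (buried)
    warning(structure(class = c("pocketeer_target_buried", "warning",
                                "condition"),
                      list(message = paste0("target ", format(target),
                                            " not on surface"),
                           call = sys.call())))
  g
}

#' Scan for Surface-Solvent-Surface events
#'
#' Runs scan lines along the configured direction set and, for every
#' maximal solvent run flanked by surface points at a flank-to-flank
#' distance of at most `max_span`, increments each run point's event count.
#' Runs touching the box boundary never count.
#'
#' @param grid A `labeled_grid` from [build_grid()].
#' @param params A [pocket_params()].
#' @return The grid with `events` filled.
#' @export
scan_sss <- function(grid, params = grid$params) {
  dirs <- .scan_directions(params$directions)
  grid$events <- cpp_scan_sss(grid$label, grid$spec$dims, grid$spec$spacing,
                              dirs, params$max_span)
  grid
}

#' Mark pocket points and split deep from surface pocket
#'
#' Solvent points with at least `min_events` scan events become pocket
#' points; those within `deep_cutoff` of bulk solvent (remaining solvent,
#' or anything beyond the box) are SURFACE_POCKET, the rest DEEP_POCKET.
#'
#' @param grid A `labeled_grid` with events filled.
#' @param params A [pocket_params()].
#' @return The grid with pocket labels applied.
#' @export
mark_pockets <- function(grid, params = grid$params) {
  grid$label <- cpp_mark_pockets(grid$label, grid$events, grid$spec$dims,
                                 grid$spec$spacing, params$min_events,
                                 params$deep_cutoff)
  grid
}

#' Cluster pocket points into discrete pockets
#'
#' Connected components over pocket-labelled points.  Each pocket records
#' its grid points, deep subset, volumes (`count * spacing^3`), whether it
#' touches the target residue (any point within `contact_radius` of a
#' target heavy atom), and its lining atoms (atom centre within
#' `vdw_radius + spacing` of a pocket point).
#'
#' @param grid A `labeled_grid` with pockets marked.
#' @param structure The structure the grid was built from.
#' @param target A `residue_selector` or string.
#' @param params A [pocket_params()].
#' @return Object of class `pocket_set`; pockets sorted by deep volume
#'   (ties: total volume, then lowest grid index).
#' @export
cluster_pockets <- function(grid, structure, target, params = grid$params) {
  if (is.character(target)) target <- parse_selector(target)
  comp <- cpp_pocket_components(grid$label, grid$spec$dims,
                                params$connectivity)
  vol1 <- params$spacing^3
  tgt <- resolve_selector(structure, target)
  tgt_xyz <- as.matrix(tgt[, c("x", "y", "z")])
  a <- .heavy_protein(structure)
  axyz <- as.matrix(a[, c("x", "y", "z")])

  ids <- setdiff(sort(unique(comp)), 0L)
  pockets <- lapply(ids, function(id) {
    pts <- which(comp == id)                    # 1-based linear indices
    deep <- pts[grid$label[pts] == GRID_DEEP_POCKET]
    pxyz <- .grid_coords(grid$spec, pts - 1L)
    # target contact
    ct <- FALSE
    for (t in seq_len(nrow(tgt_xyz))) {
      d2 <- (pxyz[, 1] - tgt_xyz[t, 1])^2 + (pxyz[, 2] - tgt_xyz[t, 2])^2 +
        (pxyz[, 3] - tgt_xyz[t, 3])^2
      if (any(d2 <= params$contact_radius^2)) { ct <- TRUE; break }
    }
    # lining atoms: centre within vdw + spacing of any pocket point
    lin <- logical(nrow(axyz))
    for (p in seq_len(nrow(pxyz))) {
      d2 <- (axyz[, 1] - pxyz[p, 1])^2 + (axyz[, 2] - pxyz[p, 2])^2 +
        (axyz[, 3] - pxyz[p, 3])^2
      lin <- lin | d2 <= (a$vdw_radius + params$spacing)^2
    }
    list(point_indices = pts, deep_point_indices = deep,
         total_volume = length(pts) * vol1, deep_volume = length(deep) * vol1,
         contacts_target = ct, lining_atoms = a$serial[lin],
         lining_rows = which(lin))
  })
  ord <- order(-vapply(pockets, `[[`, 0, "deep_volume"),
               -vapply(pockets, `[[`, 0, "total_volume"),
               vapply(pockets, function(p) min(p$point_indices), 0))
  structure(list(pockets = pockets[ord], params = params, target = target,
                 grid = grid),
            class = "pocket_set")
}

#' @export
print.pocket_set <- function(x, ...) {
  cat(sprintf("<pocket_set> %d pocket(s), target %s\n",
              length(x$pockets), format(x$target)))
  for (i in seq_along(x$pockets)) {
    p <- x$pockets[[i]]
    cat(sprintf("  [%d] deep %.0f A^3, total %.0f A^3, target contact: %s\n",
                i, p$deep_volume, p$total_volume, p$contacts_target))
  }
  invisible(x)
}

#' Full target-restricted pocket detection
#'
#' Convenience pipeline: strip hetero atoms, build and label the grid, scan
#' for Surface-Solvent-Surface events, mark and cluster pockets.
#'
#' @inheritParams build_grid
#' @return A `pocket_set`.
#' @export
detect_pockets <- function(structure, target, params = pocket_params()) {
  structure <- strip_hetero(structure)
  g <- build_grid(structure, target, params)
  g <- scan_sss(g, params)
  g <- mark_pockets(g, params)
  cluster_pockets(g, structure, target, params)
}

#' Deep pocket volume at a target residue
#'
#' The deep volume of the largest (by deep volume) pocket in contact with
#' the target residue; 0 if no pocket touches the target.
#'
#' @inheritParams build_grid
#' @return Volume in cubic Angstrom.
#' @export
deep_pocket_volume <- function(structure, target, params = pocket_params()) {
  ps <- detect_pockets(structure, target, params)
  .deep_volume_from_set(ps)
}

.deep_volume_from_set <- function(pocket_set) {
  hits <- Filter(function(p) p$contacts_target, pocket_set$pockets)
  if (length(hits) == 0L) return(0)
  hits[[1]]$deep_volume   # already sorted by deep volume
}

#' Total pocket volume at a target residue
#'
#' Total (surface + deep) volume of the largest contacting pocket; the
#' package's stand-in for external probe-based pocket volumes when gating
#' random surface sites.
#'
#' @inheritParams build_grid
#' @return Volume in cubic Angstrom.
#' @export
total_pocket_volume <- function(structure, target, params = pocket_params()) {
  ps <- detect_pockets(structure, target, params)
  hits <- Filter(function(p) p$contacts_target, ps$pockets)
  if (length(hits) == 0L) return(0)
  max(vapply(hits, `[[`, 0, "total_volume"))
}

#' Export pocket points as PDB pseudo-atoms
#'
#' Writes each pocket grid point as a HETATM with residue name PKT (deep
#' points) or SPK (surface-pocket points) for visualisation.
#'
#' @param pocket_set A `pocket_set`.
#' @param path Output PDB path (`NULL` to return lines).
#' @return PDB lines, invisibly.
#' @export
write_pocket_pdb <- function(pocket_set, path = NULL) {
  g <- pocket_set$grid
  out <- character(0)
  serial <- 0L
  for (i in seq_along(pocket_set$pockets)) {
    p <- pocket_set$pockets[[i]]
    xyz <- .grid_coords(g$spec, p$point_indices - 1L)
    deep <- p$point_indices %in% p$deep_point_indices
    for (q in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "HETATM%5d  O   %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial %% 100000L, if (deep[q]) "PKT" else "SPK", "P",
        i %% 10000L, xyz[q, 1], xyz[q, 2], xyz[q, 3], 1, 0, " O"))
    }
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
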