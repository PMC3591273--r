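# Torsion geometry: dihedral measurement, rotation about a bond axis, and
# per-residue discovery of rotatable torsions (phi / psi / chi).  Dependent
# atoms are rebuilt by rigid rotation about the torsion axis; everything
# else stays bit-identical.

# dihedral angle (degrees) defined by four points (rows of a matrix)
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# rotate rows of xyz by angle_deg about the axis through `point` along unit
# direction of `axis`
.rotate_about_axis <- function(xyz, point, axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  R <- matrix(c(
    ct + ux * ux * (1 - ct), ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy * uy * (1 - ct), uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz * uz * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
  sweep(sweep(xyz, 2L, point) %*% t(R), 2L, point, `+`)
}

# Discover the movable torsions of each residue in `mobile`:
#   chi: axis CA -> CB, moves residue atoms other than N/CA/C/O/CB
#   phi: axis N -> CA (needs preceding bonded residue), moves the residue's
#        non-(N, CA) atoms plus all later residues in the chain
#   psi: axis CA -> C (needs following bonded residue), moves the residue's
#        O plus all later residues in the chain
# Returns a list of torsion descriptors (atom row indices into the full
# atom table, hydrogens included in the moved set).
.torsion_table <- function(structure, mobile = "all") {
  a <- structure$atoms
  rt <- .residue_table(structure)
  akey <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = "\r")
  rows_of <- split(seq_len(nrow(a)), factor(akey, levels = rt$key))

  if (identical(mobile, "all")) {
    midx <- seq_len(nrow(rt))
  } else {
    if (inherits(mobile, "residue_selector")) mobile <- list(mobile)
    keys <- vapply(mobile, function(s) {
      if (is.character(s)) s <- parse_selector(s)
      paste(s$chain_id, s$residue_number, s$insertion_code, sep = "\r")
    }, "")
    midx <- match(keys, rt$key)
    if (anyNA(midx)) stop("mobile_region residue not found: ",
                          paste(keys[is.na(midx)], collapse = "; "))
  }

  find_atom <- function(rows, nm) {
    hit <- rows[a$name[rows] == nm & !a$is_h[rows]]
    if (length(hit) == 0L) NA_integer_ else hit[1]
  }

  out <- list()
  for (ri in midx) {
    rows <- rows_of[[ri]]
    nN <- find_atom(rows, "N"); nCA <- find_atom(rows, "CA")
    nC <- find_atom(rows, "C"); nCB <- find_atom(rows, "CB")
    # chain context: previous / next residue in file order, same chain
    prev_ok <- ri > 1L && rt$chain_id[ri - 1L] == rt$chain_id[ri]
    next_ok <- ri < nrow(rt) && rt$chain_id[ri + 1L] == rt$chain_id[ri]
    later <- if (ri < nrow(rt)) {
      same <- which(rt$chain_id == rt$chain_id[ri])
      unlist(rows_of[same[same > ri]], use.names = FALSE)
    } else integer(0)

    sel <- selector(rt$chain_id[ri], rt$residue_number[ri],
                    rt$insertion_code[ri])

    if (!is.na(nCA) && !is.na(nCB)) {
      side <- rows[!(a$name[rows] %in% c("N", "CA", "C", "O", "CB"))]
      if (length(side) > 0L)
        out[[length(out) + 1L]] <- list(
          residue = sel, type = "chi",
          axis_from = nCA, axis_to = nCB, moved = side)
    }
    if (!is.na(nN) && !is.na(nCA) && prev_ok) {
      moved <- c(rows[!(a$name[rows] %in% c("N", "CA"))], later)
      if (length(moved) > 0L)
        out[[length(out) + 1L]] <- list(
          residue = sel, type = "phi",
          axis_from = nN, axis_to = nCA, moved = moved)
    }
    if (!is.na(nCA) && !is.na(nC) && next_ok) {
      o_row <- find_atom(rows, "O")
      moved <- c(if (!is.na(o_row)) o_row else integer(0), later)
      if (length(moved) > 0L)
        out[[length(out) + 1L]] <- list(
          residue = sel, type = "psi",
          axis_from = nCA, axis_to = nC, moved = moved)
    }
  }
  out
}

# apply a torsion rotation in place; returns the modified structure
.apply_torsion <- function(structure, tors, angle_deg) {
  a <- structure$atoms
  p1 <- c(a$x[tors$axis_from], a$y[tors$axis_from], a$z[tors$axis_from])
  p2 <- c(a$x[tors$axis_to], a$y[tors$axis_to], a$z[tors$axis_to])
  xyz <- as.matrix(a[tors$moved, c("x", "y", "z")])
  new <- .rotate_about_axis(xyz, p2, p2 - p1, angle_deg)
  structure$atoms$x[tors$moved] <- new[, 1]
  structure$atoms$y[tors$moved] <- new[, 2]
  structure$atoms$z[tors$moved] <- new[, 3]
  structure
}

# unique torsion id for delta bookkeeping
.torsion_id <- function(tors) {
  paste0(format(tors$residue), ":", tors$type)
}

#' Backbone dihedral angles of a structure
#'
#' @param structure A `pocket_structure` with standard backbone atom names.
#' @return Data frame with one row per residue: chain, residue number,
#'   `phi` and `psi` in degrees (NA at chain termini).
#' @export
backbone_dihedrals <- function(structure) {
  a <- structure$atoms
  rt <- .residue_table(structure)
  akey <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = "\r")
  rows_of <- split(seq_len(nrow(a)), factor(akey, levels = rt$key))
  get <- function(ri, nm) {
    rows <- rows_of[[ri]]
    hit <- rows[a$name[rows] == nm]
    if (length(hit) == 0L) return(NULL)
    c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]])
  }
  n <- nrow(rt)
  phi <- psi <- rep(NA_real_, n)
  for (ri in seq_len(n)) {
    N <- get(ri, "N"); CA <- get(ri, "CA"); C <- get(ri, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (ri > 1L && rt$chain_id[ri - 1L] == rt$chain_id[ri]) {
      Cp <- get(ri - 1L, "C")
      if (!is.null(Cp)) phi[ri] <- .dihedral(Cp, N, CA, C)
    }
    if (ri < n && rt$chain_id[ri + 1L] == rt$chain_id[ri]) {
      Nn <- get(ri + 1L, "N")
      if (!is.null(Nn)) psi[ri] <- .dihedral(N, CA, C, Nn)
    }
  }
  data.frame(chain_id = rt$chain_id, residue_number = rt$residue_number,
             insertion_code = rt$insertion_code, phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}
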