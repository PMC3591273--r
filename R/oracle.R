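# Brute-force reference implementation of the grid labelling pipeline.
# Deliberately naive and written independently of the optimized C++ path:
# full point-by-point enumeration, used as the correctness oracle in tests.

#' Brute-force grid labelling (independent oracle)
#'
#' Recomputes the full labelling contract of
#' [build_grid()] + [scan_sss()] + [mark_pockets()] by naive enumeration
#' (every point against every atom; every scan line walked point by
#' point).  Refuses grids larger than 40^3 points.
#'
#' @inheritParams build_grid
#' @return A `labeled_grid` whose `label` and `events` fields must equal
#'   the optimized path's output exactly.
#' @export
brute_force_labels <- function(structure, target, params = pocket_params()) {
  if (is.character(target)) target <- parse_selector(target)
  a <- structure$atoms
  a <- a[!a$is_h & !a$is_het, , drop = FALSE]
  if (anyNA(a$vdw_radius)) stop("radii not assigned")

  # box: cube on the target heavy-atom centroid (independent re-derivation)
  tgt <- resolve_selector(structure, target)
  cen <- c(mean(tgt$x), mean(tgt$y), mean(tgt$z))
  keep <- sqrt((a$x - cen[1])^2 + (a$y - cen[2])^2 + (a$z - cen[3])^2) <=
    params$capture_radius
  cap <- if (any(keep)) a[keep, , drop = FALSE] else tgt
  half <- max(c(abs(cap$x - cen[1]), abs(cap$y - cen[2]),
                abs(cap$z - cen[3]))) + params$padding
  h <- ceiling(half / params$spacing)
  nx <- ny <- nz <- 2L * as.integer(h) + 1L
  if (as.double(nx) * ny * nz > 40^3)
    stop("grid too large for brute-force oracle (", nx, "^3 > 40^3)")
  origin <- cen - h * params$spacing
  sp <- params$spacing

  gx <- origin[1] + (0:(nx - 1L)) * sp
  gy <- origin[2] + (0:(ny - 1L)) * sp
  gz <- origin[3] + (0:(nz - 1L)) * sp
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))  # linear index order

  # PROTEIN occupancy: every point against every atom
  lab <- integer(nrow(pts))
  for (t in seq_len(nrow(a))) {
    d2 <- (pts[, 1] - a$x[t])^2 + (pts[, 2] - a$y[t])^2 + (pts[, 3] - a$z[t])^2
    lab[d2 <= a$vdw_radius[t]^2] <- 1L
  }

  arr <- array(lab, dim = c(nx, ny, nz))
  # SURFACE: protein point with a solvent-class 26-neighbour (out of box
  # counts as solvent)
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
    if (arr[i, j, k] != 1L) next
    surf <- FALSE
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || ii > nx || jj < 1 || jj > ny || kk < 1 || kk > nz) {
        surf <- TRUE
      } else if (arr[ii, jj, kk] == 0L) surf <- TRUE
    }
    if (surf) arr[i, j, k] <- 2L
  }

  # SSS scan
  dirs <- .scan_directions(params$directions)
  ev <- array(0L, dim = c(nx, ny, nz))
  for (d in seq_len(nrow(dirs))) {
    di <- dirs[d, 1]; dj <- dirs[d, 2]; dk <- dirs[d, 3]
    step_len <- sp * sqrt(sum(dirs[d, ]^2))
    for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
      # line start: predecessor outside the box
      pi_ <- i - di; pj <- j - dj; pk <- k - dk
      if (pi_ >= 1 && pi_ <= nx && pj >= 1 && pj <= ny && pk >= 1 && pk <= nz)
        next
      # walk the line
      line <- matrix(0L, nrow = 0L, ncol = 3L)
      ci <- i; cj <- j; ck <- k
      while (ci >= 1 && ci <= nx && cj >= 1 && cj <= ny && ck >= 1 && ck <= nz) {
        line <- rbind(line, c(ci, cj, ck))
        ci <- ci + di; cj <- cj + dj; ck <- ck + dk
      }
      L <- nrow(line)
      labline <- vapply(seq_len(L),
                        function(q) arr[line[q, 1], line[q, 2], line[q, 3]], 0L)
      t <- 1L
      while (t <= L) {
        if (labline[t] != 0L) { t <- t + 1L; next }
        s <- t
        while (t <= L && labline[t] == 0L) t <- t + 1L
        e <- t - 1L
        if (s == 1L || e == L) next
        if (labline[s - 1L] != 2L || labline[e + 1L] != 2L) next
        if ((e - s + 2L) * step_len > params$max_span) next
        onb <- FALSE
        for (q in s:e)
          if (any(line[q, ] == 1L) || line[q, 1] == nx ||
              line[q, 2] == ny || line[q, 3] == nz) onb <- TRUE
        if (onb) next
        for (q in s:e)
          ev[line[q, 1], line[q, 2], line[q, 3]] <-
            ev[line[q, 1], line[q, 2], line[q, 3]] + 1L
      }
    }
  }

  # pocket marking: candidate if solvent with enough events; deep unless
  # within deep_cutoff of bulk solvent (or of the box exterior)
  cand <- arr == 0L & ev >= params$min_events
  bulkm <- arr == 0L & !cand
  bulk_idx <- which(bulkm, arr.ind = TRUE)
  bulk_xyz <- cbind(origin[1] + (bulk_idx[, 1] - 1L) * sp,
                    origin[2] + (bulk_idx[, 2] - 1L) * sp,
                    origin[3] + (bulk_idx[, 3] - 1L) * sp)
  cand_idx <- which(cand, arr.ind = TRUE)
  if (nrow(cand_idx) > 0L) {
    for (q in seq_len(nrow(cand_idx))) {
      i <- cand_idx[q, 1]; j <- cand_idx[q, 2]; k <- cand_idx[q, 3]
      px <- origin[1] + (i - 1L) * sp
      py <- origin[2] + (j - 1L) * sp
      pz <- origin[3] + (k - 1L) * sp
      # nearest exterior lattice point lies one step beyond a face
      d_ext <- sp * min(i, nx - i + 1L, j, ny - j + 1L, k, nz - k + 1L)
      near <- d_ext <= params$deep_cutoff
      if (!near && nrow(bulk_xyz) > 0L) {
        d2 <- (bulk_xyz[, 1] - px)^2 + (bulk_xyz[, 2] - py)^2 +
          (bulk_xyz[, 3] - pz)^2
        near <- any(d2 <= params$deep_cutoff^2)
      }
      arr[i, j, k] <- if (near) 3L else 4L
    }
  }

  spec <- list(origin = origin, spacing = sp, dims = c(nx, ny, nz),
               centroid = cen, extent_rule = "oracle")
  .new_grid(spec, as.integer(arr), as.integer(ev), params)
}
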