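#' Monte Carlo sampler configuration
#'
#' One run is a Metropolis chain over sidechain (chi) and backbone
#' (phi/psi) torsions; an ensemble is built from the final conformation of
#' each of `n_runs` independent runs (seeded substreams), mirroring
#' ensembles collected from many independent relax-style trajectories.
#'
#' @param n_steps Proposals per run.
#' @param n_runs Independent runs (1000 at production scale; scale down for
#'   tests).
#' @param kT Metropolis temperature factor, model energy units.
#' @param move_mix Named probabilities for `sidechain_chi` and
#'   `backbone_phi_psi` moves (must sum to 1).
#' @param max_chi_step Maximum sidechain torsion perturbation, degrees.
#' @param max_bb_step Maximum backbone torsion perturbation, degrees.
#' @param mobile_region `"all"` or a list of residue selectors / strings.
#' @param seed Integer master seed.
#' @param pocket_eval_stride Re-evaluate the deep volume every this many
#'   accepted steps (stale value reused otherwise); > 1 trades bias
#'   fidelity for speed.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(n_steps = 500L, n_runs = 1000L, kT = 1.0,
                      move_mix = c(sidechain_chi = 0.7,
                                   backbone_phi_psi = 0.3),
                      max_chi_step = 30, max_bb_step = 3,
                      mobile_region = "all", seed = 1L,
                      pocket_eval_stride = 1L) {
  stopifnot(n_steps >= 0, n_runs >= 1, kT > 0,
            abs(sum(move_mix) - 1) < 1e-9, max_chi_step >= 0,
            max_bb_step >= 0, pocket_eval_stride >= 1)
  stopifnot(all(c("sidechain_chi", "backbone_phi_psi") %in% names(move_mix)))
  structure(list(n_steps = as.integer(n_steps), n_runs = as.integer(n_runs),
                 kT = kT, move_mix = move_mix, max_chi_step = max_chi_step,
                 max_bb_step = max_bb_step, mobile_region = mobile_region,
                 seed = as.integer(seed),
                 pocket_eval_stride = as.integer(pocket_eval_stride)),
            class = "mc_config")
}

# deterministic per-run seed derived from the master seed (kept < 2^31)
.run_seed <- function(seed, run_id) {
  as.integer((as.double(seed) * 48271 + run_id * 7919) %% 2147483647)
}

# index torsions by residue for the residue-first move draw
.move_index <- function(torsions) {
  res <- vapply(torsions, function(t) format(t$residue), "")
  ures <- unique(res)
  list(residues = ures,
       chi = lapply(ures, function(r)
         which(res == r & vapply(torsions, function(t) t$type == "chi", TRUE))),
       bb = lapply(ures, function(r)
         which(res == r & vapply(torsions, function(t) t$type != "chi", TRUE))))
}

# Draw one move under the current RNG: a residue uniformly from the mobile
# region, then (by move_mix) either its sidechain chi or its backbone
# (phi, psi) pair, each angle uniform within the cap.  Residues lacking
# the drawn torsion kind trigger an internal redraw.
.draw_move <- function(midx, config) {
  for (attempt in 1:1000) {
    ri <- sample.int(length(midx$residues), 1L)
    want_chi <- runif(1) < config$move_mix[["sidechain_chi"]]
    pool <- if (want_chi) midx$chi[[ri]] else midx$bb[[ri]]
    if (length(pool) == 0L) {
      # residue lacks the drawn torsion kind (GLY/ALA chi): redraw; if the
      # kind is absent from the whole mobile region and the mix never
      # draws the other kind, the proposal degenerates to a no-op
      none_anywhere <- if (want_chi) all(lengths(midx$chi) == 0L)
        else all(lengths(midx$bb) == 0L)
      other_p <- if (want_chi) 1 - config$move_mix[["sidechain_chi"]]
        else config$move_mix[["sidechain_chi"]]
      if (none_anywhere && other_p == 0) return(list())
      next
    }
    maxstep <- if (want_chi) config$max_chi_step else config$max_bb_step
    return(lapply(pool, function(ti)
      list(ti = ti, delta = runif(1, -maxstep, maxstep))))
  }
  stop("no movable torsion of the requested kind in mobile_region")
}

#' Propose one Monte Carlo move
#'
#' Draws a torsion (sidechain chi with probability
#' `move_mix["sidechain_chi"]`, else a backbone phi/psi) from the mobile
#' region and perturbs it by a uniform angle within the move-size cap.
#' All atoms outside the rotated set are bit-identical to the input.
#' Residues lacking the drawn torsion kind are redrawn internally.
#'
#' @param structure A `pocket_structure`.
#' @param config An [mc_config()].
#' @return The proposed structure, with the move description in
#'   `attr(, "move")` (torsion id, angle).
#' @export
propose_move <- function(structure, config = mc_config()) {
  torsions <- .torsion_table(structure, config$mobile_region)
  if (length(torsions) == 0L) stop("no movable torsions in mobile_region")
  midx <- .move_index(torsions)
  mvs <- .draw_move(midx, config)
  out <- structure
  for (mv in mvs) out <- .apply_torsion(out, torsions[[mv$ti]], mv$delta)
  attr(out, "move") <- lapply(mvs, function(mv)
    list(id = .torsion_id(torsions[[mv$ti]]),
         type = torsions[[mv$ti]]$type, delta = mv$delta))
  out
}

#' Run biased or unbiased Metropolis Monte Carlo
#'
#' Each run uses an independent RNG substream derived from
#' `(config$seed, run_id)`, starts from `structure`, and applies Metropolis
#' acceptance on the total energy (base + pocket bias).  The deep pocket
#' volume entering the bias is re-evaluated on a proposal only when
#' `pocket_eval_stride` accepted steps have passed since the last
#' evaluation; otherwise the stale value is used (and the bias then cancels
#' from the acceptance test).  The final conformation of every run is
#' recorded with a freshly evaluated energy breakdown.
#'
#' @param structure Starting `pocket_structure`, radii assigned.
#' @param config An [mc_config()].
#' @param spec A [bias_spec()] (use level `"none"` for unbiased runs; the
#'   final deep volume is still reported).
#' @param energy An [energy_config()].
#' @return An `mc_ensemble` with one conformation per run.
#' @export
run_mc <- function(structure, config = mc_config(), spec,
                   energy = energy_config()) {
  torsions <- .torsion_table(structure, config$mobile_region)
  if (length(torsions) == 0L) stop("no movable torsions in mobile_region")
  midx <- .move_index(torsions)
  tids <- vapply(torsions, .torsion_id, "")

  # static context for the fast matrix-based inner loop
  at <- structure$atoms
  if (anyNA(at$vdw_radius[!at$is_h])) stop("radii not assigned")
  X0 <- as.matrix(at[, c("x", "y", "z")])
  idx_e <- which(!at$is_h)                       # energy: heavy atoms
  idx_g <- which(!at$is_h & !at$is_het)          # grid: heavy polymer
  ctx <- .pair_context(at[idx_e, , drop = FALSE])
  rad_e <- at$vdw_radius[idx_e]
  rad_g <- at$vdw_radius[idx_g]
  tgt <- resolve_selector(structure, spec$target)
  tgt_g <- match(tgt$row, idx_g)
  if (anyNA(tgt_g)) stop("target residue has no grid-eligible atoms")
  p <- spec$params
  dirs <- .scan_directions(p$directions)
  pair_e <- function(X) cpp_pair_energy(X[idx_e, , drop = FALSE], rad_e,
                                        ctx$res_ord, ctx$is_bb,
                                        energy$clash_factor, energy$k_clash,
                                        energy$contact_reward,
                                        energy$contact_pad)
  vol_of <- function(X) cpp_deep_volume(X[idx_g, , drop = FALSE], rad_g,
                                        tgt_g, p$spacing, p$max_span,
                                        p$deep_cutoff, p$min_events,
                                        p$connectivity, dirs,
                                        p$contact_radius, p$capture_radius,
                                        p$padding)
  rotate_rows <- function(X, tors, angle) {
    p1 <- X[tors$axis_from, ]
    p2 <- X[tors$axis_to, ]
    X[tors$moved, ] <- .rotate_about_axis(X[tors$moved, , drop = FALSE],
                                          p2, p2 - p1, angle)
    X
  }
  start_pair <- pair_e(X0)

  run_one <- function(run_id) {
    set.seed(.run_seed(config$seed, run_id))
    X <- X0
    deltas <- setNames(numeric(length(tids)), tids)
    cur_pair <- start_pair
    cur_vol <- if (spec$enabled) vol_of(X) else NA_real_
    since_eval <- 0L
    accepted <- 0L

    if (config$n_steps > 0) for (step in seq_len(config$n_steps)) {
      mvs <- .draw_move(midx, config)
      Xp <- X
      nd <- deltas
      for (mv in mvs) {
        tors <- torsions[[mv$ti]]
        Xp <- rotate_rows(Xp, tors, mv$delta)
        nd[[.torsion_id(tors)]] <- nd[[.torsion_id(tors)]] + mv$delta
      }
      new_pair <- pair_e(Xp)
      e_old <- cur_pair$clash + cur_pair$contact +
        energy$k_torsion * sum(deltas^2)
      e_new <- new_pair$clash + new_pair$contact +
        energy$k_torsion * sum(nd^2)
      fresh <- spec$enabled && since_eval >= config$pocket_eval_stride - 1L
      if (spec$enabled) {
        new_vol <- if (fresh) vol_of(Xp) else cur_vol
        e_old <- e_old + spec$weight * cur_vol
        e_new <- e_new + spec$weight * new_vol
      }
      dE <- e_new - e_old
      if (dE <= 0 || runif(1) < exp(-dE / config$kT)) {
        X <- Xp
        deltas <- nd
        cur_pair <- new_pair
        accepted <- accepted + 1L
        if (spec$enabled) {
          if (fresh) { cur_vol <- new_vol; since_eval <- 0L }
          else since_eval <- since_eval + 1L
        }
      }
    }

    cur <- structure
    cur$atoms$x <- X[, 1]; cur$atoms$y <- X[, 2]; cur$atoms$z <- X[, 3]
    vol <- vol_of(X)
    base <- cur_pair$clash + cur_pair$contact +
      energy$k_torsion * sum(deltas^2)
    bias <- if (spec$enabled) spec$weight * vol else 0
    list(structure = cur,
         energy = .energy_breakdown(base, bias, vol),
         run_id = run_id, step_id = config$n_steps,
         torsion_deltas = deltas,
         acceptance_ratio = if (config$n_steps > 0)
           accepted / config$n_steps else NA_real_)
  }

  confs <- lapply(seq_len(config$n_runs), run_one)
  structure(list(conformations = confs, config = config, bias_spec = spec,
                 energy_config = energy),
            class = "mc_ensemble")
}

#' @export
print.mc_ensemble <- function(x, ...) {
  v <- ensemble_volumes(x)
  cat(sprintf("<mc_ensemble> %d runs x %d steps, bias %s; deep volume mean %.1f A^3 (max %.0f)\n",
              length(x$conformations), x$config$n_steps, x$bias_spec$level,
              mean(v), max(v)))
  invisible(x)
}

#' Deep volumes of an ensemble's conformations
#' @param ensemble An `mc_ensemble`.
#' @return Numeric vector, cubic Angstrom.
#' @export
ensemble_volumes <- function(ensemble) {
  vapply(ensemble$conformations, function(cf) cf$energy$deep_volume, 0)
}

#' Re-score an ensemble without the biasing term
#'
#' Recomputes every conformation's energy from its stored structure and
#' torsion history, for fair biased-vs-unbiased comparison.
#'
#' @param ensemble An `mc_ensemble`.
#' @param bias_disabled If `TRUE` (default) the bias component is zeroed;
#'   otherwise it is re-evaluated from the stored bias specification.
#' @return List of `energy_breakdown` objects, one per conformation.
#' @export
rescore_ensemble <- function(ensemble, bias_disabled = TRUE) {
  if (length(ensemble$conformations) == 0L) stop("empty ensemble")
  spec <- ensemble$bias_spec
  lapply(ensemble$conformations, function(cf) {
    base <- base_energy(cf$structure, ensemble$energy_config,
                        cf$torsion_deltas)
    vol <- cf$energy$deep_volume
    bias <- if (!bias_disabled && spec$enabled) spec$weight * vol else 0
    .energy_breakdown(base, bias, vol)
  })
}
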