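#' Simplified base-energy model configuration
#'
#' A deliberately simple, fully documented stand-in for an all-atom force
#' field, used so that the pocket-volume bias has something physical to
#' compete against.  Three terms over heavy atoms:
#' \itemize{
#'   \item soft-sphere clash: for pairs with \eqn{d < f (r_i + r_j)},
#'     \eqn{k_{clash} (f (r_i+r_j) - d)^2};
#'   \item contact reward: `contact_reward` (negative) per pair with
#'     \eqn{f (r_i+r_j) \le d \le r_i + r_j + pad};
#'   \item torsion restraint: \eqn{k_{tors} \Delta^2} per perturbed torsion,
#'     \eqn{\Delta} in degrees from the input structure.
#' }
#' Pairs within one residue, or between sequence-adjacent residues where
#' both atoms are backbone (N, CA, C, O), are excluded from the first two
#' terms.
#'
#' @param k_clash Clash constant, units/Angstrom^2.
#' @param clash_factor Fraction `f` of the radius sum below which a pair
#'   clashes.
#' @param contact_reward Reward (negative) per contact pair.
#' @param contact_pad Outer contact range beyond the radius sum, Angstrom.
#' @param k_torsion Torsion restraint constant, units/degree^2.
#' @return Object of class `energy_config`.
#' @export
energy_config <- function(k_clash = 10, clash_factor = 0.8,
                          contact_reward = -0.1, contact_pad = 1.5,
                          k_torsion = 0.01) {
  structure(list(k_clash = k_clash, clash_factor = clash_factor,
                 contact_reward = contact_reward, contact_pad = contact_pad,
                 k_torsion = k_torsion),
            class = "energy_config")
}

# per-atom residue ordinal for the bonded-pair exclusion: consecutive
# ordinals only for residues that are sequence-adjacent (same chain,
# residue numbers differing by one); chain breaks and numbering gaps get
# a gap of two so they are never treated as bonded
.pair_context <- function(atoms) {
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               sep = "\r")
  first <- !duplicated(key)
  ukey <- key[first]
  uchain <- atoms$chain_id[first]
  unum <- atoms$residue_number[first]
  n <- length(ukey)
  inc <- if (n > 1)
    ifelse(uchain[-1] == uchain[-n] & unum[-1] - unum[-n] == 1L, 1L, 2L)
  else integer(0)
  ord <- cumsum(c(1L, inc))[match(key, ukey)]
  list(res_ord = as.integer(ord),
       is_bb = atoms$name %in% c("N", "CA", "C", "O"))
}

#' Base (unbiased) energy of a structure
#'
#' @param structure A `pocket_structure` with radii assigned.
#' @param config An [energy_config()].
#' @param torsion_deltas Numeric vector of cumulative torsion deviations
#'   (degrees) from the reference input structure; `NULL` or empty for an
#'   unperturbed structure.
#' @return Energy in model units.
#' @export
base_energy <- function(structure, config = energy_config(),
                        torsion_deltas = NULL) {
  comp <- .base_components(structure, config, torsion_deltas)
  comp$clash + comp$contact + comp$torsion
}

.base_components <- function(structure, config, torsion_deltas = NULL) {
  a <- structure$atoms[!structure$atoms$is_h, , drop = FALSE]
  if (anyNA(a$vdw_radius)) stop("radii not assigned; call assign_radii()")
  ctx <- .pair_context(a)
  pe <- cpp_pair_energy(as.matrix(a[, c("x", "y", "z")]), a$vdw_radius,
                        ctx$res_ord, ctx$is_bb,
                        config$clash_factor, config$k_clash,
                        config$contact_reward, config$contact_pad)
  tors <- if (is.null(torsion_deltas) || length(torsion_deltas) == 0L) 0
  else config$k_torsion * sum(torsion_deltas^2)
  list(clash = pe$clash, contact = pe$contact, torsion = tors,
       n_contacts = pe$n_contacts)
}

#' Pocket-volume bias specification
#'
#' The biasing term is linear in the deep pocket volume at the target
#' residue: `weight * deep_volume`, with the moderate weight -0.25 energy
#' units per cubic Angstrom and the strong weight tenfold (-2.5).
#'
#' @param target A `residue_selector` or "CHAIN:RESNUM" string.
#' @param level `"moderate"`, `"strong"`, or `"none"` (disabled).
#' @param weight Override the level's weight (must be <= 0 when enabled).
#' @param params [pocket_params()] used for the volume evaluation.
#' @return Object of class `bias_spec`.
#' @export
bias_spec <- function(target, level = c("moderate", "strong", "none"),
                      weight = NULL, params = pocket_params()) {
  level <- match.arg(level)
  if (is.character(target)) target <- parse_selector(target)
  enabled <- level != "none"
  if (is.null(weight))
    weight <- switch(level, moderate = -0.25, strong = -2.5, none = 0)
  if (enabled && weight > 0)
    stop("bias weight must be <= 0 when enabled (the bias rewards volume)")
  structure(list(weight = weight, target = target, params = params,
                 enabled = enabled, level = level),
            class = "bias_spec")
}

#' Pocket bias energy of a structure
#'
#' @param structure A `pocket_structure` with radii assigned.
#' @param spec A [bias_spec()].
#' @return `weight * deep_pocket_volume`, or 0 when disabled.
#' @export
pocket_bias <- function(structure, spec) {
  if (!spec$enabled) return(0)
  spec$weight * deep_pocket_volume(structure, spec$target, spec$params)
}

#' Total energy with breakdown
#'
#' @inheritParams base_energy
#' @param spec A [bias_spec()].
#' @return An `energy_breakdown`: list with `base`, `bias`,
#'   `total = base + bias`, and `deep_volume` (evaluated regardless of
#'   whether the bias is enabled, so unbiased ensembles still report
#'   volumes).
#' @export
total_energy <- function(structure, config = energy_config(), spec,
                         torsion_deltas = NULL) {
  base <- base_energy(structure, config, torsion_deltas)
  vol <- deep_pocket_volume(structure, spec$target, spec$params)
  bias <- if (spec$enabled) spec$weight * vol else 0
  .energy_breakdown(base, bias, vol)
}

.energy_breakdown <- function(base, bias, deep_volume) {
  structure(list(base = base, bias = bias, total = base + bias,
                 deep_volume = deep_volume),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> total %.3f = base %.3f + bias %.3f (deep %.0f A^3)\n",
              x$total, x$base, x$bias, x$deep_volume))
  invisible(x)
}
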