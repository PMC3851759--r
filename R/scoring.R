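# Empirical atom-probe scoring in pKd units, with the multiple-instance
# max-pose rule. All distances are heavy-atom referenced; hydrogens are
# excluded from scoring.

#' Default scoring parameters
#'
#' Per atom-probe pair at center distance d with contact distance
#' d0 = atom vdW radius + probe contact radius:
#' \itemize{
#'   \item hydrophobic (hydrophobic atom x steric probe):
#'     `wh * ramp(d; d0-0.3, d0, d0+1.5)` - a piecewise-linear tent peaking
#'     at ideal contact;
#'   \item polar (donor atom x acceptor probe and vice versa;
#'     donor_acceptor atoms match both):
#'     `wp * ramp(d; 1.9, 2.9, 3.9) * max(0, cos(theta))^2`, theta the angle
#'     between the probe direction and the probe-to-atom vector;
#'   \item interpenetration penalty (all pairs):
#'     `-wc * max(0, (d0 - 0.5) - d)^2`.
#' }
#'
#' @param wh hydrophobic weight (pKd per ideal contact), default 0.10.
#' @param wp polar weight, default 0.35.
#' @param wc clash weight, default 2.0.
#' @param steric_radius,polar_radius default probe contact radii (Angstrom).
#' @param polar_lo,polar_ideal,polar_hi polar ramp nodes (Angstrom).
#' @param dedupe_radius same-type probe deduplication radius (Angstrom).
#' @export
score_params <- function(wh = 0.10, wp = 0.35, wc = 2.0,
                         steric_radius = 1.7, polar_radius = 1.4,
                         polar_lo = 1.9, polar_ideal = 2.9, polar_hi = 3.9,
                         dedupe_radius = 0.5) {
  list(wh = wh, wp = wp, wc = wc, steric_radius = steric_radius,
       polar_radius = polar_radius, polar_lo = polar_lo,
       polar_ideal = polar_ideal, polar_hi = polar_hi,
       dedupe_radius = dedupe_radius)
}

# Probe data frame for any scoring target. A ProteinPocket is scored by
# converting its typed atoms to implicit probes of matching class
# (donor_acceptor atoms become one donor and one acceptor probe); polar
# directions point from the atom toward the cognate-ligand centroid.
target_probes <- function(target, params = score_params()) {
  if (inherits(target, "pm_pocketmol")) {
    if (!nrow(target$probes)) stop("empty pocketmol target")
    return(target$probes)
  }
  if (!inherits(target, "pm_pocket"))
    stop("target must be a pm_pocketmol or pm_pocket")
  a <- target$atoms[!target$atoms$is_hydrogen, , drop = FALSE]
  if (!nrow(a)) stop("empty pocket target")
  ctr <- colMeans(pose_heavy_coords(target$cognate_ligand))
  rows <- list()
  add <- function(sel, type, radius) {
    if (!any(sel)) return()
    xyz <- as.matrix(a[sel, c("x", "y", "z")])
    dir <- NULL
    if (type != "steric") {
      dir <- sweep(-xyz, 2, ctr, "+")
      nrm <- sqrt(rowSums(dir^2))
      nrm[nrm < 1e-9] <- 1
      dir <- dir / nrm
    }
    rows[[length(rows) + 1L]] <<- probe_rows(type, xyz, dir, radius)
  }
  add(a$interaction_class == "hydrophobic", "steric", params$steric_radius)
  add(a$interaction_class %in% c("donor", "donor_acceptor"), "donor",
      params$polar_radius)
  add(a$interaction_class %in% c("acceptor", "donor_acceptor"), "acceptor",
      params$polar_radius)
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) stop("pocket target has no typed atoms")
  out
}

probe_cpp_args <- function(probes) {
  dir <- as.matrix(probes[, c("dx", "dy", "dz")])
  dir[is.na(dir)] <- 0
  list(P = as.matrix(probes[, c("x", "y", "z")]),
       ptype = ptype_code(probes$type), pdir = dir,
       prad = as.numeric(probes$radius))
}

atom_cpp_args <- function(mol) {
  hv <- heavy_idx(mol)
  list(idx = hv, aclass = class_code(mol$atoms$interaction_class[hv]),
       avdw = mol$atoms$vdw_radius[hv])
}

#' Score a single pose against a pocketmol or protein pocket
#'
#' @param p a `pm_pose`.
#' @param target a `pm_pocketmol` or `pm_pocket`.
#' @param params scoring parameters from [score_params()].
#' @return a `pm_score` list: hydrophobic_term, polar_term, penalty_term,
#'   total (= their sum), and per-probe `contrib` decomposition (pKd).
#' @export
score_pose <- function(p, target, params = score_params()) {
  pr <- target_probes(target, params)
  pa <- probe_cpp_args(pr)
  aa <- atom_cpp_args(p$mol)
  res <- cpp_score_terms(p$coords[aa$idx, , drop = FALSE], aa$aclass,
                         aa$avdw, pa$P, pa$ptype, pa$pdir, pa$prad,
                         params$wh, params$wp, params$wc, params$polar_lo,
                         params$polar_ideal, params$polar_hi)
  structure(list(hydrophobic_term = res$hydrophobic_term,
                 polar_term = res$polar_term,
                 penalty_term = res$penalty_term,
                 total = res$hydrophobic_term + res$polar_term +
                   res$penalty_term,
                 contrib = res$contrib),
            class = "pm_score")
}

#' @export
print.pm_score <- function(x, ...) {
  cat(sprintf("<pm_score> total %.3f (H %.3f, polar %.3f, penalty %.3f)\n",
              x$total, x$hydrophobic_term, x$polar_term, x$penalty_term))
  invisible(x)
}

# n_poses x n_probes matrix of per-probe contributions for poses of one
# molecule (all poses must share the typing of poses[[1]]$mol).
contrib_matrix <- function(poses, probes, params = score_params()) {
  aa <- atom_cpp_args(poses[[1]]$mol)
  pa <- probe_cpp_args(probes)
  coords <- lapply(poses, function(p) p$coords[aa$idx, , drop = FALSE])
  cpp_contrib_matrix(coords, aa$aclass, aa$avdw, pa$P, pa$ptype, pa$pdir,
                     pa$prad, params$wh, params$wp, params$wc,
                     params$polar_lo, params$polar_ideal, params$polar_hi)
}

#' Multiple-instance ligand score
#'
#' The score of a ligand is the maximum pose score over its pose ensemble;
#' the maximal-scoring pose defines the ligand's bound-pose estimate.
#' Ties are broken by pose index.
#'
#' @param poses nonempty list of `pm_pose` for one molecule.
#' @param target a `pm_pocketmol` or `pm_pocket`.
#' @param params scoring parameters.
#' @return list(best_pose, score, index).
#' @export
ligand_score <- function(poses, target, params = score_params()) {
  stopifnot(length(poses) >= 1)
  totals <- vapply(poses, function(p) score_pose(p, target, params)$total,
                   numeric(1))
  i <- which.max(totals)  # first max: ties by pose index
  list(best_pose = poses[[i]], score = totals[i], index = i)
}

#' Intramolecular strain penalty
#'
#' Zero for clash-free poses; otherwise `-wc * depth^2` where depth is the
#' worst violation of the 70\% vdW-sum contact limit over nonbonded
#' heavy-atom pairs (graph distance >= 3). Monotone in the worst clash depth.
#'
#' @param p a `pm_pose`.
#' @param params scoring parameters (uses `wc`).
#' @param frac clash threshold as a fraction of the radii sum.
#' @return penalty <= 0 (pKd).
#' @export
strain_penalty <- function(p, params = score_params(), frac = 0.7) {
  prs <- nonbonded_pairs(p$mol)
  if (!nrow(prs)) return(0)
  r <- p$mol$atoms$vdw_radius
  d <- sqrt(rowSums((p$coords[prs[, 1], , drop = FALSE] -
                       p$coords[prs[, 2], , drop = FALSE])^2))
  depth <- max(0, max(frac * (r[prs[, 1]] + r[prs[, 2]]) - d))
  -params$wc * depth^2
}
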