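# Evaluation statistics: rank correlation with permutation p-values, error
# metrics, pose RMSD, and the pocket/probe concordance analysis.

#' Kendall rank correlation with permutation p-value
#'
#' Tau is the tie-corrected (tau-b) pairwise-concordance statistic; the
#' p-value is a seeded two-sided permutation test:
#' `p = (1 + #permutations with |tau*| >= |tau|) / (n_perm + 1)`.
#'
#' @param pred,obs equal-length numeric vectors (length >= 3).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list(tau, p).
#' @export
kendall_tau <- function(pred, obs, n_perm = 9999, seed = 1) {
  stopifnot(length(pred) == length(obs), length(pred) >= 3)
  if (length(unique(pred)) < 2 || length(unique(obs)) < 2)
    stop("kendall_tau undefined for constant vectors")
  tau <- stats::cor(pred, obs, method = "kendall")
  p <- with_seed(seed, {
    hits <- 0L
    for (b in seq_len(n_perm)) {
      t2 <- stats::cor(pred, sample(obs), method = "kendall")
      if (abs(t2) >= abs(tau) - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (n_perm + 1)
  })
  list(tau = tau, p = p)
}

#' Mean absolute error
#' @param pred,obs equal-length nonempty numeric vectors.
#' @export
mean_abs_error <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  if (!length(pred)) stop("empty input")
  mean(abs(pred - obs))
}

#' Heavy-atom pose RMSD in the common frame
#'
#' No re-superposition and no graph-symmetry correction: all poses live in
#' the fixed pre-aligned frame and benchmark molecules are asymmetric by
#' construction. Hydrogens are excluded.
#'
#' @param a,b `pm_pose` objects of the same molecule (same atom ordering).
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  if (nrow(a$coords) != nrow(b$coords))
    stop("atom-count mismatch between poses")
  rmsd_direct(pose_heavy_coords(a), pose_heavy_coords(b))
}

#' Partition pocket atoms by ligand contact participation
#'
#' A pocket atom contacts a ligand when the minimum over the ligand's heavy
#' atoms of (center distance - radii sum) is below `surface_cut`. For
#' congruent pocket ensembles (equal atom counts) the surface distance is
#' pooled as the minimum over variants per atom index; otherwise atoms of
#' all variants are pooled individually. The high group contains atoms in
#' contact with at least `high_frac` of the ligands, the low group atoms
#' with at least one contact but no more than `low_frac` of the ligands.
#'
#' @param pockets list of `pm_pocket` (co-aligned with the poses).
#' @param reference_poses list of ligand `pm_pose` (e.g. crystal poses).
#' @param surface_cut contact surface distance (Angstrom, default 0.5).
#' @param high_frac,low_frac participation fractions (defaults 0.9, 0.1).
#' @return list(high_group, low_group): data frames of pocket atoms with a
#'   `participation` column, plus `participation` for all atoms.
#' @export
contact_partition <- function(pockets, reference_poses, surface_cut = 0.5,
                              high_frac = 0.9, low_frac = 0.1) {
  counts <- vapply(pockets, function(pk) nrow(pk$atoms), integer(1))
  congruent <- length(unique(counts)) == 1 && length(pockets) > 1
  atom_tabs <- lapply(pockets, function(pk)
    pk$atoms[, c("element", "interaction_class", "vdw_radius", "x", "y", "z")])
  surf_dist <- function(atoms) {
    # atoms x ligands matrix of minimum surface distances
    vapply(reference_poses, function(rp) {
      lx <- pose_heavy_coords(rp)
      lr <- rp$mol$atoms$vdw_radius[heavy_idx(rp$mol)]
      vapply(seq_len(nrow(atoms)), function(i) {
        d <- sqrt(colSums((t(lx) - c(atoms$x[i], atoms$y[i], atoms$z[i]))^2))
        min(d - (atoms$vdw_radius[i] + lr))
      }, numeric(1))
    }, numeric(nrow(atoms)))
  }
  if (congruent) {
    sd_list <- lapply(atom_tabs, surf_dist)
    sd_min <- Reduce(pmin, sd_list)
    atoms <- atom_tabs[[1]]
  } else {
    atoms <- do.call(rbind, atom_tabs)
    sd_min <- surf_dist(atoms)
  }
  contact <- matrix(sd_min < surface_cut, nrow = nrow(atoms))
  part <- rowMeans(contact)
  atoms$participation <- part
  nlig <- length(reference_poses)
  high <- atoms[part >= high_frac, , drop = FALSE]
  low <- atoms[part > 0 & part <= low_frac + 1e-12, , drop = FALSE]
  list(high_group = high, low_group = low, participation = part)
}

#' Distance from pocket atoms to the nearest matching-type probe
#'
#' Matching follows the structure-filter rule: hydrophobic atoms match
#' steric probes; donor atoms match donor probes; acceptor atoms match
#' acceptor probes; donor_acceptor atoms match either polar probe type.
#' Atoms with no matching probe get +Inf.
#'
#' @param atoms data frame with interaction_class, x, y, z columns.
#' @param pm a `pm_pocketmol`.
#' @return numeric vector, one distance (Angstrom) per atom.
#' @export
nearest_probe_distance <- function(atoms, pm) {
  pr <- pm$probes
  match_types <- list(hydrophobic = "steric", donor = "donor",
                      acceptor = "acceptor",
                      donor_acceptor = c("donor", "acceptor"),
                      neutral = character(0))
  vapply(seq_len(nrow(atoms)), function(i) {
    ty <- match_types[[atoms$interaction_class[i]]]
    sel <- pr$type %in% ty
    if (!any(sel)) return(Inf)
    min(sqrt((pr$x[sel] - atoms$x[i])^2 + (pr$y[sel] - atoms$y[i])^2 +
               (pr$z[sel] - atoms$z[i])^2))
  }, numeric(1))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum ECDF gap; p is the asymptotic two-sample value.
#'
#' @param x,y nonempty numeric vectors.
#' @return list(D, p).
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
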