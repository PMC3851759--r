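# Docking-lite: sample and locally optimize rigid placements of a
# conformer ensemble against a pocketmol or protein pocket. Flexibility
# enters through the conformer ensemble; torsions are not optimized
# during fitting.

fit_objective <- function(mol, target_probes_df, params) {
  aa <- atom_cpp_args(mol)
  pa <- probe_cpp_args(target_probes_df)
  function(coords) {
    res <- cpp_score_terms(coords[aa$idx, , drop = FALSE], aa$aclass,
                           aa$avdw, pa$P, pa$ptype, pa$pdir, pa$prad,
                           params$wh, params$wp, params$wc, params$polar_lo,
                           params$polar_ideal, params$polar_hi)
    res$hydrophobic_term + res$polar_term + res$penalty_term
  }
}

# Objective over the 6 rigid parameters directly (transform + score in
# one kernel call; equivalent to fit_objective(apply_rigid(coords0, par))).
rigid_objective <- function(mol, target_probes_df, params, coords0) {
  aa <- atom_cpp_args(mol)
  pa <- probe_cpp_args(target_probes_df)
  A0 <- coords0[aa$idx, , drop = FALSE]
  ctr <- colMeans(coords0)
  function(par)
    cpp_rigid_score(par, A0, ctr, aa$aclass, aa$avdw, pa$P, pa$ptype,
                    pa$pdir, pa$prad, params$wh, params$wp, params$wc,
                    params$polar_lo, params$polar_ideal, params$polar_hi)
}

#' Flexibly fit a molecule to a target
#'
#' Starting placements are each conformer aligned by principal axes to the
#' target probe cloud (8 orientation variants: 4 proper sign variants, each
#' with and without a quarter-turn about the third axis) plus seeded
#' jittered translations up to `n_starts` total per conformer. Each start
#' is refined by Nelder-Mead over the 6 rigid degrees of freedom. Poses are
#' pooled, deduplicated at 0.25 Angstrom heavy-atom RMSD, and ranked by
#' pose score plus intramolecular strain, descending. Deterministic given
#' `seed`.
#'
#' @param mol a `pm_mol` with conformers.
#' @param target `pm_pocketmol` or `pm_pocket`.
#' @param n_starts placement starts per conformer (default 12).
#' @param n_out maximum poses returned (default 20).
#' @param seed integer seed.
#' @param params scoring parameters.
#' @return list of `pm_pose` (provenance "docked") with `$score` set to
#'   score + strain.
#' @export
fit_to_target <- function(mol, target, n_starts = 12, n_out = 20, seed = 1,
                          params = score_params()) {
  stopifnot(length(mol$conformers) >= 1)
  prdf <- target_probes(target, params)
  obj <- fit_objective(mol, prdf, params)
  pxyz <- as.matrix(prdf[, c("x", "y", "z")])
  ctr <- colMeans(pxyz)
  V <- if (nrow(pxyz) >= 3) principal_axes(pxyz) else diag(3)
  hv <- heavy_idx(mol)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  quarter <- rot_xyz(c(0, 0, pi / 2))
  src <- if (inherits(target, "pm_pocket")) target$id else NA_character_

  cands <- list()
  with_seed(seed, {
    for (ci in seq_along(mol$conformers)) {
      conf <- mol$conformers[[ci]]
      strain <- strain_penalty(pose(mol, conf, "conformer"), params)
      U <- principal_axes(conf[hv, , drop = FALSE])
      cc <- sweep(conf, 2, colMeans(conf[hv, , drop = FALSE]))
      starts <- list()
      for (s in signs) {
        R0 <- V %*% diag(s) %*% t(U)
        starts[[length(starts) + 1L]] <- sweep(cc %*% t(R0), 2, ctr, "+")
        R1 <- V %*% quarter %*% diag(s) %*% t(U)
        starts[[length(starts) + 1L]] <- sweep(cc %*% t(R1), 2, ctr, "+")
      }
      while (length(starts) < n_starts) {
        base <- starts[[sample.int(8, 1)]]
        starts[[length(starts) + 1L]] <-
          sweep(base, 2, stats::rnorm(3, 0, 0.75), "+")
      }
      starts <- starts[seq_len(min(n_starts, length(starts)))]
      for (st in starts) {
        coords <- st
        sc <- obj(st)
        # restart the simplex until converged (it stalls early)
        for (round in 1:3) {
          robj <- rigid_objective(mol, prdf, params, coords)
          opt <- stats::optim(rep(0, 6), function(par) -robj(par),
                              method = "Nelder-Mead",
                              control = list(maxit = 400, reltol = 1e-7))
          if (-opt$value <= sc + 1e-3) break
          coords <- apply_rigid(coords, opt$par)
          sc <- -opt$value
        }
        cands[[length(cands) + 1L]] <-
          list(coords = coords, val = sc + strain, conf = ci)
      }
    }
  })
  ord <- order(-vapply(cands, `[[`, numeric(1), "val"),
               vapply(cands, `[[`, numeric(1), "conf"))
  cands <- cands[ord]
  kept <- list()
  for (cd in cands) {
    dup <- any(vapply(kept, function(k)
      rmsd_direct(k$coords[hv, , drop = FALSE],
                  cd$coords[hv, , drop = FALSE]) < 0.25, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- cd
    if (length(kept) >= n_out) break
  }
  lapply(kept, function(cd)
    pose(mol, cd$coords, "docked", score = cd$val, source_pocket = src))
}

#' Local rigid-body pose refinement
#'
#' Nelder-Mead over the 6 rigid degrees of freedom, with the translation
#' tethered to `tether` Angstrom of the input placement. The returned pose
#' never scores below the input pose.
#'
#' @param p a `pm_pose`.
#' @param target `pm_pocketmol` or `pm_pocket`.
#' @param tether maximum translation (Angstrom, default 2).
#' @param params scoring parameters.
#' @param max_rounds simplex restart cap (the simplex stalls well before
#'   the optimum on this landscape; restarts continue until converged).
#' @return refined `pm_pose` (provenance "refined") with `$score` set.
#' @export
local_refine <- function(p, target, tether = 2.0, params = score_params(),
                         max_rounds = 6) {
  prdf <- target_probes(target, params)
  obj <- fit_objective(p$mol, prdf, params)
  start <- p$coords
  best <- start
  s_best <- obj(start)
  # restart the simplex until converged: Nelder-Mead stalls when the
  # simplex collapses well before the optimum
  hv <- heavy_idx(p$mol)
  for (round in seq_len(max_rounds)) {
    robj <- rigid_objective(p$mol, prdf, params, best)
    cum_shift <- colMeans(best[hv, , drop = FALSE]) -
      colMeans(start[hv, , drop = FALSE])
    pen_obj <- function(par) {
      excess <- max(0, sqrt(sum((cum_shift + par[4:6])^2)) - tether)
      -robj(par) + 1e3 * excess^2
    }
    opt <- stats::optim(rep(0, 6), pen_obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-8))
    cc <- apply_rigid(best, opt$par)
    s1 <- obj(cc)
    shift <- sqrt(sum((colMeans(cc[hv, , drop = FALSE]) -
                         colMeans(start[hv, , drop = FALSE]))^2))
    if (s1 <= s_best + 1e-4 || shift > tether) break
    best <- cc
    s_best <- s1
  }
  pose(p$mol, best, "refined", score = s_best,
       source_pocket = p$source_pocket)
}

#' Multi-structure fitting
#'
#' Fits a molecule against each pocket of an ensemble, pools the poses with
#' their source-pocket record, deduplicates at 0.25 Angstrom heavy-atom
#' RMSD, and retains the top `n_out` by score (default 100, the standard
#' multi-structure docking retention).
#'
#' @param mol a `pm_mol`.
#' @param pockets nonempty list of `pm_pocket`.
#' @param n_out pose retention cap (default 100).
#' @param n_starts,seed,params passed to [fit_to_target()].
#' @return list of `pm_pose` with `$source_pocket` set.
#' @export
multi_structure_fit <- function(mol, pockets, n_out = 100, n_starts = 12,
                                seed = 1, params = score_params()) {
  stopifnot(length(pockets) >= 1)
  pool <- list()
  for (k in seq_along(pockets)) {
    ps <- fit_to_target(mol, pockets[[k]], n_starts = n_starts,
                        n_out = n_out, seed = seed + k - 1, params = params)
    pool <- c(pool, ps)
  }
  hv <- heavy_idx(mol)
  ord <- order(-vapply(pool, `[[`, numeric(1), "score"))
  pool <- pool[ord]
  kept <- list()
  for (p in pool) {
    dup <- any(vapply(kept, function(k)
      rmsd_direct(k$coords[hv, , drop = FALSE],
                  p$coords[hv, , drop = FALSE]) < 0.25, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- p
    if (length(kept) >= n_out) break
  }
  kept
}
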