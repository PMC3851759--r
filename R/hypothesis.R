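# Seed alignment hypothesis generation (ligand-only and structure-guided)
# and representative pocket selection.

## ---- 2D path fingerprints (seed-ligand diversity) -------------------------

# Hashed linear-path fingerprint: all simple heavy-atom paths up to
# `maxlen` atoms, encoded as element/bond-order strings (canonical
# direction), hashed into `nbits` buckets.
path_fingerprint <- function(mol, maxlen = 5, nbits = 512) {
  el <- mol$atoms$element
  hv <- which(el != "H")
  nb <- bond_adjacency(mol)
  ord <- matrix(0L, nrow(mol$atoms), nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
      ord[i, j] <- ord[j, i] <- mol$bonds[r, 3]
    }
  }
  paths <- character(0)
  walk <- function(pth) {
    if (length(pth) >= 2) {
      fwd <- paste(el[pth], collapse = "")
      bonds <- vapply(seq_len(length(pth) - 1), function(k)
        ord[pth[k], pth[k + 1]], integer(1))
      fwd <- paste0(fwd, paste(bonds, collapse = ""))
      rev_ <- paste0(paste(el[rev(pth)], collapse = ""),
                     paste(rev(bonds), collapse = ""))
      paths <<- c(paths, min(fwd, rev_))
    }
    if (length(pth) >= maxlen) return()
    for (w in nb[[pth[length(pth)]]]) {
      if (el[w] == "H" || w %in% pth) next
      walk(c(pth, w))
    }
  }
  for (a in hv) walk(a)
  paths <- c(paths, el[hv])  # single-atom features
  bits <- unique(vapply(paths, function(s) {
    h <- 0
    for (c in utf8ToInt(s)) h <- (h * 31 + c) %% nbits
    h + 1L
  }, numeric(1)))
  bits
}

tanimoto <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Select seed ligands for the alignment hypothesis
#'
#' Greedy selection by descending pKi subject to pairwise 2D path-
#' fingerprint Tanimoto at most `diversity_cap`; if the cap cannot be
#' satisfied, falls back to the top-n by pKi. pKi ties are broken by
#' molecule id.
#'
#' @param records data frame with molecule_id and pki columns (or a list of
#'   ActivityRecord-like lists).
#' @param mols list of `pm_mol` covering the record ids.
#' @param n number of seeds (2 or 3).
#' @param diversity_cap maximum pairwise Tanimoto (default 0.85).
#' @return list of `pm_mol`, most active first.
#' @export
select_seed_ligands <- function(records, mols, n = 3, diversity_cap = 0.85) {
  if (!is.data.frame(records))
    records <- data.frame(
      molecule_id = vapply(records, `[[`, character(1), "molecule_id"),
      pki = vapply(records, `[[`, numeric(1), "pki"))
  stopifnot(n %in% 2:3, nrow(records) >= n)
  ids <- vapply(mols, `[[`, character(1), "id")
  records <- records[order(-records$pki, records$molecule_id), ]
  records <- records[records$molecule_id %in% ids, ]
  fps <- list()
  fp_of <- function(id) {
    if (is.null(fps[[id]]))
      fps[[id]] <<- path_fingerprint(mols[[match(id, ids)]])
    fps[[id]]
  }
  chosen <- character(0)
  for (id in records$molecule_id) {
    if (length(chosen) >= n) break
    ok <- all(vapply(chosen, function(c2)
      tanimoto(fp_of(id), fp_of(c2)) <= diversity_cap, logical(1)))
    if (ok) chosen <- c(chosen, id)
  }
  if (length(chosen) < n) chosen <- records$molecule_id[seq_len(n)]
  mols[match(chosen, ids)]
}

## ---- representative pocket selection --------------------------------------

# Fixed-length shape feature: sorted pocket-atom distances to the
# ensemble's mean cognate-ligand centroid, padded/truncated to length 64.
pocket_feature <- function(pk, ref_center, len = 64) {
  xyz <- pocket_coords(pk)
  d <- sort(sqrt(colSums((t(xyz) - ref_center)^2)))
  if (length(d) >= len) d[seq_len(len)] else c(d, rep(d[length(d)],
                                                      len - length(d)))
}

#' Select representative pocket structures by k-means
#'
#' Pockets are clustered on a fixed-length shape feature (sorted atom
#' distances to the ensemble's mean cognate-ligand centroid); the member
#' nearest each cluster centroid is returned. Deterministic given `seed`
#' (k-means with 10 seeded restarts).
#'
#' @param pockets list of `pm_pocket`.
#' @param k number of representatives (k <= |pockets|).
#' @param seed integer seed.
#' @return list of `pm_pocket`, in original input order.
#' @export
select_representative_pockets <- function(pockets, k, seed = 1) {
  if (k > length(pockets))
    stop("k exceeds the number of pockets")
  if (k == length(pockets)) return(pockets)
  ctr <- colMeans(do.call(rbind, lapply(pockets, function(p)
    colMeans(pose_heavy_coords(p$cognate_ligand)))))
  feat <- do.call(rbind, lapply(pockets, pocket_feature, ref_center = ctr))
  km <- with_seed(seed, stats::kmeans(feat, centers = k, nstart = 10))
  reps <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(km$cluster == cl)
    d <- sqrt(rowSums((feat[members, , drop = FALSE] -
                         matrix(km$centers[cl, ], length(members), ncol(feat),
                                byrow = TRUE))^2))
    reps[cl] <- members[which.min(d)]
  }
  pockets[sort(reps)]
}

## ---- hypothesis optimization ----------------------------------------------

#' Exact pose-combination optimizer
#'
#' Exhaustively maximizes the sum of pairwise similarities over one pose
#' choice per molecule, plus similarities to a set of fixed poses
#' (fixed-fixed pairs are constant and omitted). Exact for all problem
#' sizes up to `cap` combinations.
#'
#' @param cand_poses list (one element per molecule) of lists of `pm_pose`.
#' @param fixed_poses optional list of fixed `pm_pose` (e.g. cognate
#'   crystal ligands).
#' @param cap maximum number of combinations (default 1e7).
#' @return list(selection = chosen indices, poses, objective).
#' @export
optimize_pose_combination <- function(cand_poses, fixed_poses = list(),
                                      cap = 1e7) {
  n <- length(cand_poses)
  sizes <- vapply(cand_poses, length, integer(1))
  stopifnot(n >= 1, all(sizes >= 1))
  if (prod(sizes) > cap)
    stop("pose-combination count ", format(prod(sizes), scientific = TRUE),
         " exceeds the brute-force cap; reduce per-molecule pose counts")
  # pairwise similarity tables between candidate sets
  S <- vector("list", n * n); dim(S) <- c(n, n)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      m <- matrix(0, sizes[i], sizes[j])
      for (a in seq_len(sizes[i]))
        for (b in seq_len(sizes[j]))
          m[a, b] <- sim_total(cand_poses[[i]][[a]], cand_poses[[j]][[b]])
      S[[i, j]] <- m
    }
  }
  # per-candidate similarity to the fixed poses
  cfix <- lapply(seq_len(n), function(i) {
    if (!length(fixed_poses)) return(rep(0, sizes[i]))
    vapply(cand_poses[[i]], function(p)
      sum(vapply(fixed_poses, function(f) sim_total(p, f), numeric(1))),
      numeric(1))
  })
  grid <- as.matrix(expand.grid(lapply(sizes, seq_len)))
  obj <- rep(0, nrow(grid))
  for (i in seq_len(n)) obj <- obj + cfix[[i]][grid[, i]]
  if (n >= 2) {
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        obj <- obj + S[[i, j]][cbind(grid[, i], grid[, j])]
  }
  best <- which.max(obj)
  sel <- as.integer(grid[best, ])
  list(selection = sel,
       poses = lapply(seq_len(n), function(i) cand_poses[[i]][[sel[i]]]),
       objective = obj[best])
}

hypothesis_result <- function(poses, objective, mode) {
  structure(list(selected_poses = poses, objective = objective, mode = mode),
            class = "pm_hypothesis")
}

#' @export
print.pm_hypothesis <- function(x, ...) {
  cat("<pm_hypothesis>", x$mode, ":", length(x$selected_poses),
      sprintf("poses, objective %.3f\n", x$objective))
  invisible(x)
}

# Recompute a hypothesis objective from its selected poses and fixed poses.
hypothesis_objective <- function(poses, fixed_poses = list()) {
  tot <- 0
  n <- length(poses)
  if (n >= 2)
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        tot <- tot + sim_total(poses[[i]], poses[[j]])
  for (p in poses)
    for (f in fixed_poses)
      tot <- tot + sim_total(p, f)
  tot
}

# Canonical-frame candidate poses: each conformer centered at the origin
# with principal axes on the lab axes, 4 proper sign variants.
canonical_candidates <- function(mol, n_max = 12) {
  hv <- heavy_idx(mol)
  out <- list()
  for (ci in seq_along(mol$conformers)) {
    conf <- mol$conformers[[ci]]
    U <- principal_axes(conf[hv, , drop = FALSE])
    cc <- sweep(conf, 2, colMeans(conf[hv, , drop = FALSE]))
    for (s in list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))) {
      R <- diag(s) %*% t(U)
      out[[length(out) + 1L]] <- pose(mol, cc %*% t(R), "conformer")
      if (length(out) >= n_max) return(out)
    }
  }
  out
}

#' Ligand-only alignment hypothesis
#'
#' Maximizes the mutual 3D similarity of 2-3 seed ligands over a sampled
#' pose grid (conformers x canonical orientations), exactly over the grid,
#' followed by a round of per-molecule rigid coordinate-ascent refinement.
#'
#' @param seeds list of 2-3 `pm_mol`.
#' @param n_poses_each candidate poses per seed (default 12).
#' @param seed integer seed.
#' @return a `pm_hypothesis` (mode "ligand_only").
#' @export
hypothesis_ligand_based <- function(seeds, n_poses_each = 12, seed = 1) {
  stopifnot(length(seeds) %in% 2:3)
  cands <- lapply(seeds, canonical_candidates, n_max = n_poses_each)
  res <- optimize_pose_combination(cands)
  poses <- res$poses
  # coordinate-ascent rigid polish (first pose stays fixed as the anchor)
  for (i in seq_along(poses)[-1]) {
    others <- poses[-i]
    fobj <- function(par) {
      p <- pose(poses[[i]]$mol, apply_rigid(poses[[i]]$coords, par),
                "similarity_aligned")
      -sum(vapply(others, function(o) sim_total(p, o), numeric(1)))
    }
    opt <- stats::optim(rep(0, 6), fobj, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-8))
    if (-opt$value > sum(vapply(others, function(o)
      sim_total(poses[[i]], o), numeric(1))))
      poses[[i]] <- pose(poses[[i]]$mol,
                         apply_rigid(poses[[i]]$coords, opt$par),
                         "similarity_aligned")
  }
  hypothesis_result(poses, hypothesis_objective(poses), "ligand_only")
}

#' Structure-guided alignment hypothesis
#'
#' Each seed ligand is docked into the pocket ensemble by multi-structure
#' fitting (up to `n_poses` poses retained per seed, default 100); the
#' cognate crystal ligands are appended as fixed single-pose molecules;
#' the single pose per seed maximizing the total pairwise similarity
#' (seed-seed and seed-cognate pairs) is found by exhaustive enumeration.
#'
#' @param seeds list of 2-3 `pm_mol`.
#' @param pockets nonempty list of `pm_pocket` with cognate ligands.
#' @param seed integer seed.
#' @param n_poses docked pose retention per seed (default 100).
#' @param n_starts docking starts per conformer.
#' @param params scoring parameters.
#' @param cap brute-force combination cap.
#' @return a `pm_hypothesis` (mode "structure_guided"); the cognate poses
#'   used are attached as attribute "fixed_poses".
#' @export
hypothesis_structure_guided <- function(seeds, pockets, seed = 1,
                                        n_poses = 100, n_starts = 12,
                                        params = score_params(),
                                        cap = 1e7) {
  stopifnot(length(seeds) %in% 2:3, length(pockets) >= 1)
  fixed <- lapply(pockets, `[[`, "cognate_ligand")
  cands <- lapply(seq_along(seeds), function(i)
    multi_structure_fit(seeds[[i]], pockets, n_out = n_poses,
                        n_starts = n_starts, seed = seed + 100 * i,
                        params = params))
  stopifnot(all(vapply(cands, length, integer(1)) >= 1))
  res <- optimize_pose_combination(cands, fixed_poses = fixed, cap = cap)
  poses <- res$poses
  # continuous rigid polish of each seed pose against the fixed cognate
  # anchors and the other seeds (two coordinate-ascent rounds)
  for (round in 1:2) {
    for (i in seq_along(poses)) {
      others <- c(poses[-i], fixed)
      cur <- sum(vapply(others, function(o) sim_total(poses[[i]], o),
                        numeric(1)))
      opt <- stats::optim(rep(0, 6), function(par) {
        p <- pose(poses[[i]]$mol, apply_rigid(poses[[i]]$coords, par),
                  "similarity_aligned")
        -sum(vapply(others, function(o) sim_total(p, o), numeric(1)))
      }, method = "Nelder-Mead",
      control = list(maxit = 200, reltol = 1e-7))
      if (-opt$value > cur + 1e-9)
        poses[[i]] <- pose(poses[[i]]$mol,
                           apply_rigid(poses[[i]]$coords, opt$par),
                           "similarity_aligned")
    }
  }
  out <- hypothesis_result(poses, hypothesis_objective(poses, fixed),
                           "structure_guided")
  attr(out, "fixed_poses") <- fixed
  out
}
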