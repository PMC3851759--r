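# 3D molecular similarity by Gaussian overlap, and similarity-driven
# flexible alignment onto a pose hypothesis.

# Overlap inputs for one pose: heavy-atom coords, per-atom Gaussian sd
# (vdw/2), and donor/acceptor index masks (donor_acceptor counts as both).
sim_sets <- function(p) {
  hv <- heavy_idx(p$mol)
  cls <- p$mol$atoms$interaction_class[hv]
  list(coords = p$coords[hv, , drop = FALSE],
       sigma = p$mol$atoms$vdw_radius[hv] / 2,
       don = cls %in% c("donor", "donor_acceptor"),
       acc = cls %in% c("acceptor", "donor_acceptor"))
}

overlap_between <- function(sa, sb, maska, maskb) {
  if (!any(maska) || !any(maskb)) return(0)
  cpp_overlap(sa$coords[maska, , drop = FALSE], sa$sigma[maska],
              sb$coords[maskb, , drop = FALSE], sb$sigma[maskb])
}

#' 3D pose similarity
#'
#' Gaussian-overlap similarity between two placed poses in the common frame.
#' The shape component is `2 O(A,B) / (O(A,A) + O(B,B))` where O is the
#' summed pairwise overlap integral of isotropic Gaussians centered on
#' heavy atoms with standard deviation vdW/2. The polar component is
#' computed identically over donor and acceptor atoms only (same-type
#' pairs contribute; donor_acceptor atoms count as both types); it is 1
#' when neither molecule has polar atoms. The total is the mean of the two
#' components: symmetric, in [0, 1], self-similarity 1, and invariant under
#' any rigid transform applied jointly to both poses.
#'
#' @param a,b `pm_pose` objects.
#' @return a `pm_similarity` list: total, shape_component, polar_component.
#' @export
pose_similarity <- function(a, b) {
  sa <- sim_sets(a); sb <- sim_sets(b)
  if (!nrow(sa$coords) || !nrow(sb$coords))
    stop("pose_similarity: empty molecule")
  alln <- rep(TRUE, nrow(sa$coords)); allm <- rep(TRUE, nrow(sb$coords))
  oab <- overlap_between(sa, sb, alln, allm)
  oaa <- overlap_between(sa, sa, alln, alln)
  obb <- overlap_between(sb, sb, allm, allm)
  shape <- 2 * oab / (oaa + obb)
  pab <- overlap_between(sa, sb, sa$don, sb$don) +
    overlap_between(sa, sb, sa$acc, sb$acc)
  paa <- overlap_between(sa, sa, sa$don, sa$don) +
    overlap_between(sa, sa, sa$acc, sa$acc)
  pbb <- overlap_between(sb, sb, sb$don, sb$don) +
    overlap_between(sb, sb, sb$acc, sb$acc)
  polar <- if (paa + pbb <= 0) 1 else 2 * pab / (paa + pbb)
  structure(list(total = (shape + polar) / 2, shape_component = shape,
                 polar_component = polar),
            class = "pm_similarity")
}

#' @export
print.pm_similarity <- function(x, ...) {
  cat(sprintf("<pm_similarity> total %.3f (shape %.3f, polar %.3f)\n",
              x$total, x$shape_component, x$polar_component))
  invisible(x)
}

sim_total <- function(a, b) pose_similarity(a, b)$total

#' Pairwise similarity matrix
#'
#' @param poses list of >= 2 `pm_pose`.
#' @return symmetric matrix with unit diagonal, entries in [0, 1].
#' @export
pairwise_similarity_matrix <- function(poses) {
  n <- length(poses)
  stopifnot(n >= 2)
  m <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m[i, j] <- m[j, i] <- sim_total(poses[[i]], poses[[j]])
    }
  }
  m
}

# Apply a 6-DOF rigid parameter vector (3 Euler angles, 3 translations)
# to a coordinate set, rotating about its own centroid.
apply_rigid <- function(coords, par) {
  transform_coords(coords, par[1:3], par[4:6], colMeans(coords))
}

# Candidate rigid placements of `coords` aligning its principal axes to
# target axes V at target center, over the 4 proper sign variants.
axis_placements <- function(coords, V, center, variants = 4) {
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  U <- principal_axes(coords)
  cc <- sweep(coords, 2, colMeans(coords))
  lapply(signs[seq_len(variants)], function(s) {
    R <- V %*% diag(s) %*% t(U)
    sweep(cc %*% t(R), 2, center, "+")
  })
}

#' Similarity-driven alignment onto a pose hypothesis
#'
#' Generates rigid placements of each conformer (principal-axes
#' pre-alignment to each hypothesis pose, 4 proper sign variants), locally
#' optimizes the maximum-over-hypothesis similarity with a quasi-Newton
#' rigid-body refinement, pools, dedupes at 0.25 Angstrom RMSD, and returns
#' the top `n_out` poses ranked by descending similarity (stable ties:
#' conformer index, then variant index). Deterministic given `seed`.
#'
#' @param mol a `pm_mol` with conformers.
#' @param hypothesis nonempty list of `pm_pose`.
#' @param n_out maximum number of poses returned (default 100).
#' @param seed integer seed.
#' @param optimize logical; run the local rigid refinement (default TRUE).
#' @return list of `pm_pose` with provenance "similarity_aligned" and the
#'   achieved similarity stored in `$score`.
#' @export
align_to_hypothesis <- function(mol, hypothesis, n_out = 100, seed = 1,
                                optimize = TRUE) {
  stopifnot(length(hypothesis) >= 1, length(mol$conformers) >= 1)
  hv <- heavy_idx(mol)
  # precomputed overlap machinery: the similarity evaluated here is
  # exactly pose_similarity(), with the pose-independent self-overlap
  # terms hoisted out of the inner optimization loop
  cls <- mol$atoms$interaction_class[hv]
  sig <- mol$atoms$vdw_radius[hv] / 2
  mdon <- cls %in% c("donor", "donor_acceptor")
  macc <- cls %in% c("acceptor", "donor_acceptor")
  hyp_sets <- lapply(hypothesis, sim_sets)
  pol_self <- function(X, sg, don, acc) {
    (if (any(don)) cpp_overlap(X[don, , drop = FALSE], sg[don],
                               X[don, , drop = FALSE], sg[don]) else 0) +
      (if (any(acc)) cpp_overlap(X[acc, , drop = FALSE], sg[acc],
                                 X[acc, , drop = FALSE], sg[acc]) else 0)
  }
  hyp_self <- lapply(hyp_sets, function(ss)
    list(shape = cpp_overlap(ss$coords, ss$sigma, ss$coords, ss$sigma),
         polar = pol_self(ss$coords, ss$sigma, ss$don, ss$acc)))
  mk_objective <- function(conf) {
    A0 <- conf[hv, , drop = FALSE]
    self_shape <- cpp_overlap(A0, sig, A0, sig)
    self_polar <- pol_self(A0, sig, mdon, macc)
    function(coords) {
      A <- coords[hv, , drop = FALSE]
      best <- 0
      for (k in seq_along(hyp_sets)) {
        hs <- hyp_sets[[k]]
        oab <- cpp_overlap(A, sig, hs$coords, hs$sigma)
        shape <- 2 * oab / (self_shape + hyp_self[[k]]$shape)
        pden <- self_polar + hyp_self[[k]]$polar
        polar <- if (pden <= 0) 1 else {
          pab <- (if (any(mdon) && any(hs$don))
            cpp_overlap(A[mdon, , drop = FALSE], sig[mdon],
                        hs$coords[hs$don, , drop = FALSE],
                        hs$sigma[hs$don]) else 0) +
            (if (any(macc) && any(hs$acc))
              cpp_overlap(A[macc, , drop = FALSE], sig[macc],
                          hs$coords[hs$acc, , drop = FALSE],
                          hs$sigma[hs$acc]) else 0)
          2 * pab / pden
        }
        tot <- (shape + polar) / 2
        if (tot > best) best <- tot
      }
      best
    }
  }
  cands <- list()
  for (ci in seq_along(mol$conformers)) {
    conf <- mol$conformers[[ci]]
    objective <- mk_objective(conf)
    for (hi in seq_along(hypothesis)) {
      hcoords <- pose_heavy_coords(hypothesis[[hi]])
      V <- principal_axes(hcoords)
      ctr <- colMeans(hcoords)
      U <- principal_axes(conf[hv, , drop = FALSE])
      signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
      for (vi in seq_along(signs)) {
        s <- signs[[vi]]
        R <- V %*% diag(s) %*% t(U)
        full <- sweep(sweep(conf, 2, colMeans(conf[hv, , drop = FALSE])) %*%
                        t(R), 2, ctr, "+")
        sc <- objective(full)
        if (optimize) {
          opt <- stats::optim(rep(0, 6), function(par)
            -objective(apply_rigid(full, par)), method = "BFGS",
            control = list(maxit = 40, reltol = 1e-6))
          if (-opt$value > sc) {
            full <- apply_rigid(full, opt$par)
            sc <- -opt$value
          }
        }
        cands[[length(cands) + 1L]] <-
          list(coords = full, sim = sc, conf = ci, var = vi)
      }
    }
  }
  ord <- order(-vapply(cands, `[[`, numeric(1), "sim"),
               vapply(cands, `[[`, numeric(1), "conf"),
               vapply(cands, `[[`, numeric(1), "var"))
  cands <- cands[ord]
  kept <- list()
  for (cd in cands) {
    dup <- FALSE
    for (k in kept) {
      if (nrow(k$coords) == nrow(cd$coords) &&
          rmsd_direct(k$coords[hv, , drop = FALSE],
                      cd$coords[hv, , drop = FALSE]) < 0.25) {
        dup <- TRUE; break
      }
    }
    if (!dup) kept[[length(kept) + 1L]] <- cd
    if (length(kept) >= n_out) break
  }
  lapply(kept, function(cd)
    pose(mol, cd$coords, "similarity_aligned", score = cd$sim))
}
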