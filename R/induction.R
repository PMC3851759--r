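# The learning core: greedy probe-subset selection against training
# activities under the max-pose (multiple-instance) rule, alternating
# probe-position and ligand-pose refinement, three probe densities,
# parsimony-based model selection.

#' Create a training record
#'
#' @param mol a `pm_mol`.
#' @param pki experimental activity, -log10 molar.
#' @param ensemble nonempty list of candidate `pm_pose` for the molecule.
#' @return a `pm_training_record`; `best_pose`/`current_score` are filled
#'   once the record is scored against a pocketmol.
#' @export
training_record <- function(mol, pki, ensemble) {
  stopifnot(is.finite(pki), length(ensemble) >= 1)
  structure(list(molecule = mol, pki = pki, pose_ensemble = ensemble,
                 best_pose = ensemble[[1]], current_score = NA_real_),
            class = "pm_training_record")
}

# Re-evaluate every record against `pm` (max-pose rule); batched
# per-record kernel call instead of per-pose scoring.
rescore_training <- function(training, pm, params = score_params()) {
  lapply(training, function(rec) {
    totals <- rowSums(contrib_matrix(rec$pose_ensemble, pm$probes, params))
    i <- which.max(totals)
    rec$best_pose <- rec$pose_ensemble[[i]]
    rec$current_score <- totals[i]
    rec
  })
}

training_scores <- function(training)
  vapply(training, `[[`, numeric(1), "current_score")

training_pkis <- function(training)
  vapply(training, `[[`, numeric(1), "pki")

#' Training RMSE of a scored training set
#' @param training list of scored `pm_training_record`.
#' @export
train_rmse <- function(training)
  sqrt(mean((training_scores(training) - training_pkis(training))^2))

#' Induction configuration
#'
#' @param densities three probe-count caps (the three probe densities).
#' @param lambda probe-count regularizer (pKd^2 per probe).
#' @param max_outer_iter cap on alternating refinement iterations.
#' @param rmse_tol convergence tolerance on the training RMSE (pKd).
#' @param probe_tether maximum probe displacement during refinement
#'   (Angstrom); keeps structure-filtered probes near their justification.
#' @param seed integer seed.
#' @param parsimony_delta activity window (pKd) for the parsimony measure.
#' @param pool_cap candidate-pool cap for greedy selection (the best
#'   candidates by maximum single-pose contribution are kept).
#' @param refine_maxit Nelder-Mead iteration cap per probe refinement.
#' @export
induction_config <- function(densities = c(25, 50, 100), lambda = 0.005,
                             max_outer_iter = 10, rmse_tol = 0.05,
                             probe_tether = 1.0, seed = 1,
                             parsimony_delta = 0.5, pool_cap = 600,
                             refine_maxit = 40) {
  stopifnot(length(densities) == 3, rmse_tol > 0, lambda >= 0)
  list(densities = densities, lambda = lambda,
       max_outer_iter = max_outer_iter, rmse_tol = rmse_tol,
       probe_tether = probe_tether, seed = seed,
       parsimony_delta = parsimony_delta, pool_cap = pool_cap,
       refine_maxit = refine_maxit)
}

# Per-record pose-by-probe contribution matrices for a probe data frame.
training_contribs <- function(training, probes, params) {
  lapply(training, function(rec)
    contrib_matrix(rec$pose_ensemble, probes, params))
}

col_max <- function(M) do.call(pmax, c(asplit(M, 1), list(na.rm = FALSE)))

#' Greedy probe-subset selection
#'
#' Forward selection minimizing
#' `L = sum_i (ligand_score_i - pki_i)^2 + lambda * |subset|`,
#' re-evaluating the max-pose ligand scores after each addition, stopping
#' at `size_cap` or when no candidate reduces L, followed by one backward
#' elimination sweep. Deterministic given `seed`.
#'
#' @param pool a `pm_probepool`.
#' @param training list of `pm_training_record` with pose ensembles.
#' @param size_cap maximum number of probes.
#' @param lambda size regularizer.
#' @param seed integer seed.
#' @param params scoring parameters.
#' @param pool_cap candidate-pool cap (see [induction_config()]).
#' @return a `pm_pocketmol` (provenance follows the pool's filtered flag).
#' @export
select_probe_subset <- function(pool, training, size_cap, lambda = 0.005,
                                seed = 1, params = score_params(),
                                pool_cap = 600) {
  if (!nrow(pool$probes)) stop("empty probe pool")
  probes <- pool$probes
  C <- training_contribs(training, probes, params)
  pki <- training_pkis(training)
  n_rec <- length(training)
  # prune the candidate pool to the most individually useful probes
  if (nrow(probes) > pool_cap) {
    usefulness <- Reduce(`+`, lapply(C, function(M) apply(M, 2, max)))
    keep <- order(-usefulness)[seq_len(pool_cap)]
    keep <- sort(keep)
    probes <- probes[keep, , drop = FALSE]
    C <- lapply(C, function(M) M[, keep, drop = FALSE])
  }
  np <- nrow(probes)
  cur <- lapply(C, function(M) rep(0, nrow(M)))
  selected <- integer(0)
  remaining <- seq_len(np)
  cur_scores <- rep(0, n_rec)
  L <- sum((cur_scores - pki)^2)
  while (length(selected) < size_cap && length(remaining)) {
    loss_j <- rep(0, length(remaining))
    for (i in seq_len(n_rec)) {
      M <- C[[i]][, remaining, drop = FALSE] + cur[[i]]
      loss_j <- loss_j + (col_max(M) - pki[i])^2
    }
    Lj <- loss_j + lambda * (length(selected) + 1)
    best <- which.min(Lj)
    if (Lj[best] >= L - 1e-12) break
    j <- remaining[best]
    selected <- c(selected, j)
    for (i in seq_len(n_rec)) cur[[i]] <- cur[[i]] + C[[i]][, j]
    cur_scores <- vapply(cur, max, numeric(1))
    L <- sum((cur_scores - pki)^2) + lambda * length(selected)
    remaining <- remaining[-best]
  }
  # one backward-elimination sweep
  if (length(selected) > 1) {
    for (j in rev(selected)) {
      trial <- setdiff(selected, j)
      sc <- vapply(seq_len(n_rec), function(i)
        max(rowSums(C[[i]][, trial, drop = FALSE])), numeric(1))
      Lt <- sum((sc - pki)^2) + lambda * length(trial)
      if (Lt < L - 1e-12) {
        selected <- trial
        L <- Lt
      }
    }
  }
  if (!length(selected)) selected <- integer(0)
  prov <- if (isTRUE(pool$filtered)) "structure_guided" else "ligand_only"
  pocketmol(probes[selected, , drop = FALSE], provenance = prov,
            density_label = as.character(size_cap))
}

## ---- refinement -----------------------------------------------------------

sph_to_dir <- function(theta, phi)
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))

dir_to_sph <- function(v) c(acos(max(-1, min(1, v[3]))), atan2(v[2], v[1]))

#' Refine probe positions (and polar directions) against the activities
#'
#' Each probe is locally optimized in turn (Nelder-Mead; 3 positional DOF,
#' plus 2 angular DOF for polar probes) to reduce the training objective
#' `sum_i (ligand_score_i - pki_i)^2`, with ligand poses held fixed and
#' displacement tethered to `tether` Angstrom. Moves are accepted only if
#' the objective decreases, so the objective is non-increasing.
#'
#' @param pm a `pm_pocketmol`.
#' @param training scored training records (poses fixed).
#' @param tether maximum displacement per probe (Angstrom).
#' @param params scoring parameters.
#' @param maxit Nelder-Mead iteration cap per probe.
#' @return the refined `pm_pocketmol`.
#' @export
refine_probe_positions <- function(pm, training, tether = 1.0,
                                   params = score_params(), maxit = 40) {
  probes <- pm$probes
  if (!nrow(probes)) return(pm)
  pki <- training_pkis(training)
  D <- training_contribs(training, probes, params)
  # flattened pose list with per-pose typing, for one-call objective evals
  coords_all <- list(); acl_all <- list(); avd_all <- list()
  seg <- vector("list", length(training))
  pos0_all <- 0L
  for (i in seq_along(training)) {
    aa <- atom_cpp_args(training[[i]]$molecule)
    cc <- lapply(training[[i]]$pose_ensemble, function(p)
      p$coords[aa$idx, , drop = FALSE])
    seg[[i]] <- pos0_all + seq_along(cc)
    pos0_all <- pos0_all + length(cc)
    coords_all <- c(coords_all, cc)
    acl_all <- c(acl_all, rep(list(aa$aclass), length(cc)))
    avd_all <- c(avd_all, rep(list(aa$avdw), length(cc)))
  }
  base_flat <- unlist(lapply(seq_along(training), function(i)
    rowSums(D[[i]])))
  probe_col_flat <- function(j)
    unlist(lapply(seq_along(training), function(i) D[[i]][, j]))
  eval_probe <- function(row, base_wo) {
    pa <- probe_cpp_args(row)
    v <- cpp_single_probe_scores(coords_all, acl_all, avd_all, pa$P,
                                 pa$ptype, pa$pdir, pa$prad, params$wh,
                                 params$wp, params$wc, params$polar_lo,
                                 params$polar_ideal, params$polar_hi)
    s <- base_wo + v
    sc <- vapply(seg, function(ix) max(s[ix]), numeric(1))
    sum((sc - pki)^2)
  }
  for (j in seq_len(nrow(probes))) {
    row <- probes[j, , drop = FALSE]
    base_wo <- base_flat - probe_col_flat(j)
    pos0 <- c(row$x, row$y, row$z)
    polar <- row$type != "steric"
    par0 <- if (polar) c(pos0, dir_to_sph(c(row$dx, row$dy, row$dz)))
            else pos0
    f <- function(par) {
      if (sqrt(sum((par[1:3] - pos0)^2)) > tether) return(1e9)
      r2 <- row
      r2$x <- par[1]; r2$y <- par[2]; r2$z <- par[3]
      if (polar) {
        d <- sph_to_dir(par[4], par[5])
        r2$dx <- d[1]; r2$dy <- d[2]; r2$dz <- d[3]
      }
      eval_probe(r2, base_wo)
    }
    f0 <- eval_probe(row, base_wo)
    opt <- stats::optim(par0, f, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-7))
    if (opt$value < f0 - 1e-12) {
      probes$x[j] <- opt$par[1]
      probes$y[j] <- opt$par[2]
      probes$z[j] <- opt$par[3]
      if (polar) {
        d <- sph_to_dir(opt$par[4], opt$par[5])
        probes$dx[j] <- d[1]; probes$dy[j] <- d[2]; probes$dz[j] <- d[3]
      }
      # refresh cached contributions for the moved probe
      pa <- probe_cpp_args(probes[j, , drop = FALSE])
      v <- cpp_single_probe_scores(coords_all, acl_all, avd_all, pa$P,
                                   pa$ptype, pa$pdir, pa$prad, params$wh,
                                   params$wp, params$wc, params$polar_lo,
                                   params$polar_ideal, params$polar_hi)
      base_flat <- base_wo + v
      for (i in seq_along(training)) D[[i]][, j] <- v[seg[[i]]]
    }
  }
  pocketmol(probes, provenance = pm$provenance,
            density_label = pm$density_label)
}

#' Refine training-ligand poses against the current pocketmol
#'
#' The top `n_refine` poses of each record's ensemble are locally refined
#' (rigid, tethered); improved refinements join the ensemble and the
#' record is re-scored under the max-pose rule, so `current_score` never
#' decreases.
#'
#' @param pm a `pm_pocketmol`.
#' @param training scored training records.
#' @param params scoring parameters.
#' @param tether refinement tether (Angstrom).
#' @param n_refine how many top-scoring ensemble poses to refine.
#' @return updated training records.
#' @export
refine_training_poses <- function(pm, training, params = score_params(),
                                  tether = 2.0, n_refine = 3) {
  lapply(training, function(rec) {
    old <- if (is.na(rec$current_score))
      ligand_score(rec$pose_ensemble, pm, params)$score
      else rec$current_score
    totals <- rowSums(contrib_matrix(rec$pose_ensemble, pm$probes, params))
    top <- order(-totals)[seq_len(min(n_refine, length(totals)))]
    best_sc <- old
    for (k in top) {
      ref <- local_refine(rec$pose_ensemble[[k]], pm, tether = tether,
                          params = params)
      if (ref$score > best_sc + 1e-12) {
        rec$pose_ensemble <- c(rec$pose_ensemble, list(ref))
        rec$best_pose <- ref
        best_sc <- ref$score
      }
    }
    rec$current_score <- best_sc
    rec
  })
}

## ---- model assembly -------------------------------------------------------

new_model <- function(pm, training, config, converged) {
  m <- structure(list(pocketmol = pm, training = training,
                      train_rmse = train_rmse(training),
                      parsimony = NA_real_, config = config,
                      converged = converged),
                 class = "pm_model")
  m$parsimony <- parsimony(m, config$parsimony_delta)
  m
}

#' @export
print.pm_model <- function(x, ...) {
  cat(sprintf(
    "<pm_model> %d probes (density %s, %s), train RMSE %.3f, parsimony %.3f%s\n",
    nrow(x$pocketmol$probes), x$pocketmol$density_label,
    x$pocketmol$provenance, x$train_rmse, x$parsimony,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Model parsimony
#'
#' Mean 3D pose similarity of the final best poses over all training pairs
#' whose activities differ by at most `delta` pKd; 0 when no pair
#' qualifies. Models whose close-in-activity training molecules adopt
#' mutually similar poses are preferred at selection time.
#'
#' @param model a `pm_model` (or a list of scored training records).
#' @param delta activity window (pKd, default 0.5).
#' @return parsimony in [0, 1].
#' @export
parsimony <- function(model, delta = 0.5) {
  training <- if (inherits(model, "pm_model")) model$training else model
  n <- length(training)
  if (n < 2) return(0)
  pki <- training_pkis(training)
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(pki[i] - pki[j]) <= delta) {
        vals <- c(vals, sim_total(training[[i]]$best_pose,
                                  training[[j]]$best_pose))
      }
    }
  }
  if (!length(vals)) 0 else mean(vals)
}

#' Induce pocketmol models at three probe densities
#'
#' For each density: greedy probe-subset selection, then alternation of
#' probe-position refinement and training-pose refinement until the
#' training RMSE changes by less than `rmse_tol` or `max_outer_iter` is
#' reached. Non-convergence is flagged on the model, not an error.
#'
#' @param training list of >= 5 `pm_training_record` with pose ensembles.
#' @param pool a `pm_probepool`.
#' @param config an [induction_config()].
#' @param params scoring parameters.
#' @return list of 3 `pm_model` (one per density).
#' @export
induce <- function(training, pool, config = induction_config(),
                   params = score_params()) {
  stopifnot(length(training) >= 5)
  if (!nrow(pool$probes)) stop("empty probe pool")
  lapply(config$densities, function(cap) {
    pm <- select_probe_subset(pool, training, size_cap = cap,
                              lambda = config$lambda, seed = config$seed,
                              params = params, pool_cap = config$pool_cap)
    tr <- rescore_training(training, pm, params)
    rmse <- train_rmse(tr)
    best <- list(pm = pm, tr = tr, rmse = rmse)
    converged <- FALSE
    for (it in seq_len(config$max_outer_iter)) {
      pm <- refine_probe_positions(pm, tr, tether = config$probe_tether,
                                   params = params,
                                   maxit = config$refine_maxit)
      tr <- rescore_training(tr, pm, params)
      tr <- refine_training_poses(pm, tr, params = params)
      new_rmse <- train_rmse(tr)
      if (new_rmse < best$rmse) best <- list(pm = pm, tr = tr,
                                             rmse = new_rmse)
      if (abs(new_rmse - rmse) < config$rmse_tol) {
        converged <- TRUE
        rmse <- new_rmse
        break
      }
      rmse <- new_rmse
    }
    new_model(best$pm, best$tr, config, converged)
  })
}

#' Select the best model by parsimony
#'
#' Parsimony arbitrates among models that have actually solved the
#' fitting problem: only models whose training RMSE is within
#' `fit_slack` of the best RMSE are eligible (an under-fitted sparse
#' model scores high parsimony trivially, because unconstrained poses
#' cluster). Among the eligible models the highest parsimony wins;
#' values within `tol` are treated as numerically tied (parsimony is a
#' mean of pairwise similarities, so third-decimal differences are
#' noise), with ties broken by lower training RMSE, then lower probe
#' density.
#'
#' @param models nonempty list of `pm_model`.
#' @param fit_slack training-RMSE eligibility margin (pKd, default 0.25).
#' @param tol parsimony tie tolerance (default 0.01).
#' @export
select_best_model <- function(models, fit_slack = 0.25, tol = 0.01) {
  stopifnot(length(models) >= 1)
  pars <- vapply(models, `[[`, numeric(1), "parsimony")
  rmse <- vapply(models, `[[`, numeric(1), "train_rmse")
  dens <- vapply(models, function(m)
    suppressWarnings(as.numeric(m$pocketmol$density_label)), numeric(1))
  dens[is.na(dens)] <- Inf
  eligible <- which(rmse <= min(rmse) + fit_slack)
  tied <- eligible[pars[eligible] >= max(pars[eligible]) - tol]
  best <- tied[order(rmse[tied], dens[tied])][1]
  models[[best]]
}
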