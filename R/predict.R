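# Prediction of pKi, bound pose, and similarity-based confidence for new
# molecules against a final pocketmol model.

#' Predict activity and pose for one molecule
#'
#' The molecule is flexibly fit into the model's pocketmol; the predicted
#' pKi is the best pose's score (including intramolecular strain), and the
#' confidence is the maximum 3D pose similarity of the predicted pose to
#' any final training pose (a proxy for applicability domain).
#'
#' @param model a `pm_model`.
#' @param mol a prepared `pm_mol`.
#' @param seed integer seed for the fitting search.
#' @param n_starts fitting starts per conformer.
#' @param n_refine top-ranked fits receiving an extra local refinement.
#' @param params scoring parameters.
#' @return a `pm_prediction`: molecule_id, pki_pred, pose, confidence,
#'   nearest_training_id, breakdown (a `pm_score`).
#' @export
predict_molecule <- function(model, mol, seed = 1, n_starts = 16,
                             n_refine = 5, params = score_params()) {
  fits <- fit_to_target(mol, model$pocketmol, n_starts = n_starts,
                        n_out = max(1, n_refine), seed = seed,
                        params = params)
  if (!length(fits)) stop("fitting produced no pose for ", mol$id)
  best <- fits[[1]]
  for (f in fits) {
    r <- local_refine(f, model$pocketmol, params = params)
    sc <- r$score + strain_penalty(r, params)
    if (sc > best$score) {
      best <- r
      best$score <- sc
    }
  }
  sims <- vapply(model$training, function(rec)
    sim_total(best, rec$best_pose), numeric(1))
  k <- which.max(sims)
  structure(list(molecule_id = mol$id,
                 pki_pred = best$score,
                 pose = best,
                 confidence = sims[k],
                 nearest_training_id = model$training[[k]]$molecule$id,
                 breakdown = score_pose(best, model$pocketmol, params)),
            class = "pm_prediction")
}

#' @export
print.pm_prediction <- function(x, ...) {
  cat(sprintf("<pm_prediction> %s: pKi %.2f, confidence %.2f (nearest %s)\n",
              x$molecule_id, x$pki_pred, x$confidence,
              x$nearest_training_id))
  invisible(x)
}

#' Batch prediction
#'
#' Elementwise [predict_molecule()] with per-molecule seeds derived from
#' `seed`; order preserved. Per-molecule failures are collected in the
#' "errors" attribute and the batch continues.
#'
#' @param model a `pm_model`.
#' @param mols list of `pm_mol`.
#' @param seed integer seed.
#' @param ... passed to [predict_molecule()].
#' @return list of `pm_prediction` (failed molecules omitted), with
#'   attribute "errors" a named character vector of failure messages.
#' @export
predict_batch <- function(model, mols, seed = 1, ...) {
  out <- list()
  errs <- character(0)
  for (k in seq_along(mols)) {
    r <- tryCatch(predict_molecule(model, mols[[k]], seed = seed + k - 1,
                                   ...),
                  error = function(e) e)
    if (inherits(r, "error")) {
      errs[mols[[k]]$id] <- conditionMessage(r)
    } else {
      out[[length(out) + 1L]] <- r
    }
  }
  attr(out, "errors") <- errs
  out
}

#' Stratify predictions by confidence
#'
#' For each threshold t (descending; thresholds are nested, 0 means "all"),
#' summarizes the subset with confidence >= t: count, pKi range, mean
#' absolute error, Kendall tau with permutation p, and mean pose RMSD when
#' reference poses are supplied.
#'
#' @param results list of `pm_prediction`.
#' @param obs named numeric vector of observed pKi (names = molecule ids).
#' @param thresholds descending confidence thresholds
#'   (default c(0.7, 0.5, 0)).
#' @param reference_poses optional named list of crystal `pm_pose`.
#' @param n_perm,seed permutation settings for the tau p-value.
#' @return data frame with one row per threshold.
#' @export
stratify_by_confidence <- function(results, obs,
                                   thresholds = c(0.7, 0.5, 0),
                                   reference_poses = NULL,
                                   n_perm = 999, seed = 1) {
  stopifnot(!is.unsorted(rev(thresholds)))
  conf <- vapply(results, `[[`, numeric(1), "confidence")
  ids <- vapply(results, `[[`, character(1), "molecule_id")
  pred <- vapply(results, `[[`, numeric(1), "pki_pred")
  o <- obs[ids]
  rows <- lapply(thresholds, function(t) {
    sel <- conf >= t
    n <- sum(sel)
    mae <- if (n) mean_abs_error(pred[sel], o[sel]) else NA_real_
    tau <- p <- NA_real_
    if (n >= 3 && length(unique(o[sel])) > 1 &&
        length(unique(pred[sel])) > 1) {
      kt <- kendall_tau(pred[sel], o[sel], n_perm = n_perm, seed = seed)
      tau <- kt$tau; p <- kt$p
    }
    rmsd <- NA_real_
    if (!is.null(reference_poses) && n) {
      rs <- vapply(which(sel), function(i) {
        rp <- reference_poses[[ids[i]]]
        if (is.null(rp)) return(NA_real_)
        pose_rmsd(results[[i]]$pose, rp)
      }, numeric(1))
      rmsd <- mean(rs, na.rm = TRUE)
    }
    data.frame(confidence = t, n = n,
               pki_lo = if (n) min(o[sel]) else NA_real_,
               pki_hi = if (n) max(o[sel]) else NA_real_,
               mae = mae, tau = tau, tau_p = p, mean_rmsd = rmsd)
  })
  do.call(rbind, rows)
}
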