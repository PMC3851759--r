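# End-to-end orchestration: hypothesis -> training alignment ->
# tessellation -> (structure filter) -> induction -> parsimony selection.

#' Pipeline control settings
#'
#' @param n_seed_ligands seed ligands for the alignment hypothesis (3).
#' @param n_hyp_poses docked poses retained per seed in structure-guided
#'   hypothesis generation.
#' @param n_train_poses alignment poses retained per training ligand.
#' @param n_tess_poses top-ranked poses per active ligand used for
#'   tessellation.
#' @param k_pockets representative pocket structures selected by k-means.
#' @param n_starts fitting starts per conformer.
#' @param max_conformers conformer-ensemble cap per molecule.
#' @param active_cutoff pKi threshold defining "active" training ligands
#'   for tessellation; NULL means the training median.
#' @param induction an [induction_config()].
#' @param tessellation a [tessellation_config()].
#' @param params scoring parameters.
#' @export
pipeline_control <- function(n_seed_ligands = 3, n_hyp_poses = 40,
                             n_train_poses = 20, n_tess_poses = 3,
                             k_pockets = 5, n_starts = 12,
                             max_conformers = 5, active_cutoff = NULL,
                             induction = induction_config(),
                             tessellation = tessellation_config(),
                             params = score_params()) {
  list(n_seed_ligands = n_seed_ligands, n_hyp_poses = n_hyp_poses,
       n_train_poses = n_train_poses, n_tess_poses = n_tess_poses,
       k_pockets = k_pockets, n_starts = n_starts,
       max_conformers = max_conformers, active_cutoff = active_cutoff,
       induction = induction, tessellation = tessellation, params = params)
}

#' Build pocketmol models from training data
#'
#' Runs the full induction pipeline: seed-ligand selection, alignment
#' hypothesis (ligand-only by mutual similarity, or structure-guided by
#' multi-structure docking plus cognate poses), similarity alignment of
#' all training ligands, probe tessellation of the active poses,
#' structure-based probe filtering (structure-guided mode), induction at
#' three probe densities, and parsimony-based selection.
#'
#' @param mols list of prepared `pm_mol` training ligands.
#' @param pki named numeric vector of training activities (names are
#'   molecule ids).
#' @param pockets list of `pm_pocket` (required for structure_guided).
#' @param mode "ligand_only" or "structure_guided".
#' @param seed integer seed.
#' @param control a [pipeline_control()].
#' @param verbose log stage progress via message().
#' @return list: mode, seeds, hypothesis, training, pool (pre-filter),
#'   filtered_pool, models (3), best (`pm_model`), control, seed.
#' @export
build_pocketmol_model <- function(mols, pki, pockets = NULL,
                                  mode = c("ligand_only",
                                           "structure_guided"),
                                  seed = 1, control = pipeline_control(),
                                  verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message(sprintf(...))
  if (mode == "structure_guided" && !length(pockets))
    stop("structure_guided mode requires pocket structures")
  params <- control$params
  ids <- vapply(mols, `[[`, character(1), "id")
  stopifnot(all(ids %in% names(pki)))
  pki <- pki[ids]

  mols <- lapply(seq_along(mols), function(i)
    generate_conformers(mols[[i]], max_n = control$max_conformers,
                        seed = seed + i))
  say("prepared %d training ligands (<= %d conformers each)",
      length(mols), control$max_conformers)

  rec_df <- data.frame(molecule_id = ids, pki = as.numeric(pki))
  seeds <- select_seed_ligands(rec_df, mols, n = control$n_seed_ligands)
  say("seed ligands: %s",
      paste(vapply(seeds, `[[`, character(1), "id"), collapse = ", "))

  reps <- NULL
  if (mode == "structure_guided") {
    k <- min(control$k_pockets, length(pockets))
    reps <- select_representative_pockets(pockets, k, seed = seed)
    hyp <- hypothesis_structure_guided(seeds, reps, seed = seed,
                                       n_poses = control$n_hyp_poses,
                                       n_starts = control$n_starts,
                                       params = params)
  } else {
    hyp <- hypothesis_ligand_based(seeds, seed = seed)
  }
  say("%s hypothesis objective: %.3f", mode, hyp$objective)

  training <- lapply(seq_along(mols), function(i) {
    ens <- align_to_hypothesis(mols[[i]], hyp$selected_poses,
                               n_out = control$n_train_poses,
                               seed = seed + i)
    training_record(mols[[i]], pki[[i]], ens)
  })
  say("aligned training ligands (%d poses each max)",
      control$n_train_poses)

  cutoff <- if (is.null(control$active_cutoff)) stats::median(pki)
            else control$active_cutoff
  active <- which(pki >= cutoff)
  active_poses <- unlist(lapply(active, function(i)
    utils::head(training[[i]]$pose_ensemble, control$n_tess_poses)),
    recursive = FALSE)
  pool <- tessellate(active_poses, control$tessellation, params)
  say("tessellated %d actives -> %d probes", length(active),
      nrow(pool$probes))
  filtered <- pool
  if (mode == "structure_guided") {
    filtered <- filter_probes(pool, reps)
    say("structure filter: %d -> %d probes", nrow(pool$probes),
        nrow(filtered$probes))
    if (!nrow(filtered$probes))
      stop("structure filter removed every probe; check pocket alignment")
  }

  icfg <- control$induction
  icfg$seed <- seed
  models <- induce(training, filtered, icfg, params)
  best <- select_best_model(models)
  say("models: %s; selected density %s (parsimony %.3f, RMSE %.3f)",
      paste(sprintf("[%s] RMSE %.2f par %.2f",
                    vapply(models, function(m) m$pocketmol$density_label,
                           character(1)),
                    vapply(models, `[[`, numeric(1), "train_rmse"),
                    vapply(models, `[[`, numeric(1), "parsimony")),
            collapse = " "),
      best$pocketmol$density_label, best$parsimony, best$train_rmse)
  list(mode = mode, seeds = seeds, hypothesis = hyp, training = training,
       pool = pool, filtered_pool = filtered, pockets = reps,
       models = models, best = best, control = control, seed = seed)
}
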