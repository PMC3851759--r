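# Multi-seed structure-guidance study shared by the acceptance tests.
# One lean pipeline configuration is applied identically to both modes,
# so the paired comparison is unaffected by the problem-size scaling.

study_benchmark_config <- function() {
  benchmark_config(n_variants = 5, n_train = 10, n_congeneric_test = 2,
                   n_diverse = 8, noise_sd = 0.2, gt_size = 35)
}

study_control <- function() {
  pipeline_control(
    n_hyp_poses = 15, n_train_poses = 10, n_tess_poses = 2, n_starts = 8,
    max_conformers = 3,
    induction = induction_config(max_outer_iter = 3, pool_cap = 250,
                                 refine_maxit = 20))
}

run_study_seed <- function(seed) {
  bm <- make_benchmark(seed, study_benchmark_config())
  mols <- lapply(bm$train, function(e) e$mol)
  pki <- stats::setNames(vapply(bm$train, `[[`, numeric(1), "pki"),
                         vapply(bm$train, function(e) e$mol$id,
                                character(1)))
  div_mols <- lapply(seq_along(bm$diverse_test), function(i)
    generate_conformers(bm$diverse_test[[i]]$mol, 5, seed + 900 + i))
  dobs <- vapply(bm$diverse_test, `[[`, numeric(1), "pki")
  out <- list(seed = seed)
  for (mode in c("structure_guided", "ligand_only")) {
    fit <- build_pocketmol_model(
      mols, pki,
      pockets = if (mode == "structure_guided") bm$pockets else NULL,
      mode = mode, seed = seed, control = study_control())
    res <- predict_batch(fit$best, div_mols, seed = seed + 70,
                         n_starts = 6, n_refine = 2)
    pred <- vapply(res, `[[`, numeric(1), "pki_pred")
    conf <- vapply(res, `[[`, numeric(1), "confidence")
    rmsd <- vapply(seq_along(res), function(i)
      pose_rmsd(res[[i]]$pose, bm$diverse_test[[i]]$ref_pose), numeric(1))
    out[[mode]] <- list(pred = pred, obs = dobs, conf = conf, rmsd = rmsd,
                        mae = mean(abs(pred - dobs)),
                        mean_rmsd = mean(rmsd))
  }
  out
}

study_results <- local({
  res <- NULL
  function(seeds = 1:5) {
    if (is.null(res)) res <<- lapply(seeds, run_study_seed)
    res
  }
})
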