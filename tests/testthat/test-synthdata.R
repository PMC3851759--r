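test_that("pocket ensembles are seeded, typed, and jitter-controlled", {
  e1 <- make_pocket_ensemble(4, n_variants = 2, jitter_sd = 0)
  expect_length(e1$variants, 2)
  # zero jitter: variants identical to base
  expect_equal(e1$variants[[1]]$atoms[, c("x", "y", "z")],
               e1$base$atoms[, c("x", "y", "z")])
  expect_true(all(e1$base$atoms$interaction_class %in%
                    c("hydrophobic", "donor", "acceptor",
                      "donor_acceptor")))
  # reproducibility
  e2 <- make_pocket_ensemble(4, n_variants = 2, jitter_sd = 0)
  expect_equal(e1$base$atoms, e2$base$atoms)
  e3 <- make_pocket_ensemble(4, n_variants = 3, jitter_sd = 0.3)
  expect_length(e3$variants, 3)
  expect_gt(max(abs(e3$variants[[1]]$atoms$x - e3$base$atoms$x)), 0)
  # the wall surrounds the cognate without clashing
  expect_true(pocketmolr:::ligand_clash_free(
    e3$base$cognate_ligand$mol, e3$base$cognate_ligand$coords, e3$base))
})

test_that("ligand series: sizes, clash-free references, scaffold contrast", {
  ens <- make_pocket_ensemble(4, n_variants = 1, jitter_sd = 0.2)
  sr <- make_ligand_series(5, 12, 6, ens$base)
  expect_length(sr$congeneric, 12)
  expect_length(sr$diverse, 6)
  for (e in c(sr$congeneric, sr$diverse)) {
    expect_true(pocketmolr:::ligand_clash_free(e$mol, e$ref_pose$coords,
                                               ens$base))
  }
  # diverse scaffolds are structurally distinct from the congeneric one
  fp_cong <- pocketmolr:::path_fingerprint(sr$congeneric[[1]]$mol)
  for (e in sr$diverse) {
    tan <- pocketmolr:::tanimoto(
      pocketmolr:::path_fingerprint(e$mol), fp_cong)
    expect_lt(tan, 0.6)
  }
  # empty congeneric request is honored
  sr0 <- make_ligand_series(5, 0, 2, ens$base)
  expect_length(sr0$congeneric, 0)
})

test_that("simulated activities equal ground-truth scores plus noise", {
  ens <- make_pocket_ensemble(4, n_variants = 1, jitter_sd = 0.2)
  sr <- make_ligand_series(5, 6, 0, ens$base)
  gt <- pocketmolr:::make_ground_truth(sr, list(ens$base, ens$variants[[1]]),
                                       size = 25, seed = 2)
  acts0 <- simulate_activities(gt, sr$congeneric, noise_sd = 0, seed = 3)
  for (i in seq_along(sr$congeneric)) {
    expect_equal(acts0$pki[i],
                 min(max(score_pose(sr$congeneric[[i]]$ref_pose,
                                    gt)$total, 0), 12),
                 tolerance = 1e-9)
  }
  expect_identical(acts0, simulate_activities(gt, sr$congeneric,
                                              noise_sd = 0, seed = 3))
  # Monte-Carlo: the sample SD of pki - score approximates noise_sd
  entries <- rep(sr$congeneric[1], 200)
  acts <- simulate_activities(gt, entries, noise_sd = 0.4,
                              pki_range = c(-50, 50), seed = 9)
  expect_lt(abs(sd(acts$pki - acts$true_score) - 0.4) / 0.4, 0.2)
})

test_that("benchmarks are reproducible with disjoint splits", {
  cfg <- benchmark_config(n_variants = 2, n_train = 6,
                          n_congeneric_test = 3, n_diverse = 3,
                          gt_size = 25, noise_sd = 0)
  bm <- make_benchmark(11, cfg)
  ids <- function(z) vapply(z, function(e) e$mol$id, character(1))
  expect_length(intersect(ids(bm$train), ids(bm$congeneric_test)), 0)
  expect_length(intersect(ids(bm$train), ids(bm$diverse_test)), 0)
  bm2 <- make_benchmark(11, cfg)
  expect_equal(bm$activities, bm2$activities)
  expect_equal(bm$ground_truth$probes, bm2$ground_truth$probes)
  # activity invariant: pki = clipped ground-truth score of the reference
  for (e in bm$train) {
    expect_equal(e$pki,
                 min(max(score_pose(e$ref_pose, bm$ground_truth)$total,
                         0), 12), tolerance = 1e-9)
  }
  # ground-truth probes all survive their own structural filter
  gtpool <- probe_pool(bm$ground_truth$probes,
                       rep("gt", nrow(bm$ground_truth$probes)))
  surv <- filter_probes(gtpool, bm$pockets)
  expect_equal(nrow(surv$probes), nrow(bm$ground_truth$probes))
  cache_benchmark(bm)  # reuse in later tests
})

test_that("a written benchmark loads back through the standard readers", {
  bm <- cached_benchmark()
  td <- withr::local_tempdir()
  write_benchmark(bm, td)
  man <- jsonlite::read_json(file.path(td, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, bm$seed)
  tr <- read_molecules(file.path(td, "train.sdf"))
  expect_length(tr, length(bm$train))
  expect_equal(tr[[1]]$conformers[[1]],
               bm$train[[1]]$mol$conformers[[1]], tolerance = 1e-3,
               ignore_attr = TRUE)
  acts <- read_activities(file.path(td, "activities.csv"))
  expect_equal(acts$pki[match(tr[[1]]$id, acts$molecule_id)],
               bm$train[[1]]$pki, tolerance = 1e-6)
  pk <- read_pocket(file.path(td, "pocket_base.pdb"),
                    file.path(td, "pocket_base_ligand.sdf"),
                    pocket_cutoff = bm$config$pocket_cutoff)
  expect_equal(nrow(pk$atoms), nrow(bm$pockets[[1]]$atoms))
  expect_equal(pk$atoms$interaction_class,
               bm$pockets[[1]]$atoms$interaction_class)
  gt <- read_pocketmol(file.path(td, "ground_truth.pocketmol"))
  expect_equal(nrow(gt$probes), nrow(bm$ground_truth$probes))
})
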