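test_that("seed-ligand selection is activity-ranked with a diversity cap", {
  # three scaffolds: two near-identical, one distinct
  m1 <- hexa_mol("a1"); m2 <- hexa_mol("a2"); m3 <- chain_mol("b1")
  mols <- list(m1, m2, m3)
  rec <- data.frame(molecule_id = c("a1", "a2", "b1"),
                    pki = c(9, 8.5, 8))
  picked <- select_seed_ligands(rec, mols, n = 2, diversity_cap = 0.85)
  expect_equal(vapply(picked, `[[`, character(1), "id"), c("a1", "b1"))
  # unsatisfiable cap -> top-n fallback
  same <- list(hexa_mol("a1"), hexa_mol("a2"), hexa_mol("a3"))
  rec2 <- data.frame(molecule_id = c("a1", "a2", "a3"), pki = c(7, 9, 8))
  picked2 <- select_seed_ligands(rec2, same, n = 2, diversity_cap = 0.1)
  expect_equal(vapply(picked2, `[[`, character(1), "id"), c("a2", "a3"))
  # pKi ties broken by molecule id (stable)
  rec3 <- data.frame(molecule_id = c("zz", "aa", "mm"), pki = c(8, 8, 8))
  same3 <- list(hexa_mol("zz"), hexa_mol("aa"), hexa_mol("mm"))
  picked3 <- select_seed_ligands(rec3, same3, n = 2, diversity_cap = 0.0)
  expect_equal(vapply(picked3, `[[`, character(1), "id"), c("aa", "mm"))
})

test_that("representative pocket selection clusters shapes", {
  mk_shifted <- function(id, spread) {
    mk_pocket(id, rep("hydrophobic", 8),
              as.vector(t(pocketmolr:::fibonacci_sphere(8, spread))),
              cognate = pose(mk_mol(paste0(id, "l"), "C", c(0, 0, 0))))
  }
  tight <- lapply(1:3, function(k) mk_shifted(paste0("t", k), 4 + 0.05 * k))
  wide <- lapply(1:3, function(k) mk_shifted(paste0("w", k), 8 + 0.05 * k))
  pockets <- c(tight, wide)
  # k = |pockets| -> identity
  expect_identical(select_representative_pockets(pockets, 6, seed = 1),
                   pockets)
  reps <- select_representative_pockets(pockets, 2, seed = 1)
  ids <- vapply(reps, `[[`, character(1), "id")
  expect_equal(length(reps), 2)
  expect_true(any(startsWith(ids, "t")) && any(startsWith(ids, "w")))
  # k = 1 -> the pocket nearest the global feature centroid
  one <- select_representative_pockets(pockets, 1, seed = 1)
  expect_length(one, 1)
  expect_error(select_representative_pockets(pockets, 7, seed = 1),
               "exceeds")
})

test_that("pose-combination optimization equals exhaustive enumeration", {
  set.seed(31)
  mols <- list(hexa_mol("m1"), chain_mol("m2"), hexa_mol("m3"))
  for (rep in 1:3) {
    cands <- lapply(mols, function(m) {
      lapply(seq_len(sample(2:4, 1)), function(k)
        apply_rigid_pose(pose(m), random_rigid()))
    })
    fixed <- list(apply_rigid_pose(pose(chain_mol("fx")), random_rigid()))
    res <- optimize_pose_combination(cands, fixed)
    # independent full enumeration with double loops
    best <- -Inf
    sizes <- vapply(cands, length, integer(1))
    for (a in seq_len(sizes[1])) for (b in seq_len(sizes[2]))
      for (cc in seq_len(sizes[3])) {
        sel <- list(cands[[1]][[a]], cands[[2]][[b]], cands[[3]][[cc]])
        obj <- 0
        for (i in 1:2) for (j in (i + 1):3)
          obj <- obj + pose_similarity(sel[[i]], sel[[j]])$total
        for (p in sel) for (f in fixed)
          obj <- obj + pose_similarity(p, f)$total
        best <- max(best, obj)
      }
    expect_equal(res$objective, best, tolerance = 1e-12)
  }
  expect_error(optimize_pose_combination(
    list(rep(list(pose(hexa_mol("x"))), 40),
         rep(list(pose(hexa_mol("y"))), 40)), cap = 100),
    "cap")
})

test_that("ligand-only hypothesis superposes identical rigid molecules", {
  seeds <- list(hexa_mol("s1"), hexa_mol("s2"))
  hyp <- hypothesis_ligand_based(seeds, seed = 1)
  expect_equal(hyp$mode, "ligand_only")
  expect_equal(hyp$objective, 1.0, tolerance = 1e-6)
  expect_lt(pose_rmsd(hyp$selected_poses[[1]], hyp$selected_poses[[2]]),
            0.05)
  # objective is recomputable from the selected poses
  expect_equal(hyp$objective,
               pocketmolr:::hypothesis_objective(hyp$selected_poses),
               tolerance = 1e-9)
})

test_that("structure-guided hypothesis picks the cognate-like pose", {
  mol <- hexa_mol("sg")
  cg_pose <- pose(mol, provenance = "crystal")
  # wall atoms at the cognate's own tessellation positions (typed
  # complementary to the probes), so the cognate placement is the
  # docking optimum by construction
  wall <- tessellate(list(cg_pose),
                     tessellation_config(fine_opt = FALSE))$probes
  wall_cls <- c(steric = "hydrophobic", donor = "donor",
                acceptor = "acceptor")[wall$type]
  pk <- mk_pocket("skp", unname(wall_cls),
                  as.vector(t(as.matrix(wall[, c("x", "y", "z")]))),
                  cognate = cg_pose)
  hyp <- hypothesis_structure_guided(list(hexa_mol("sg1"),
                                          hexa_mol("sg2")),
                                     list(pk), seed = 2, n_poses = 8,
                                     n_starts = 8)
  expect_equal(hyp$mode, "structure_guided")
  expect_length(hyp$selected_poses, 2)
  # both seeds are copies of the cognate molecule: the similarity
  # objective should recover cognate-like placements
  sims <- vapply(hyp$selected_poses, function(p)
    pose_similarity(p, cg_pose)$total, numeric(1))
  expect_gt(mean(sims), 0.5)
  # objective matches recomputation including the fixed cognate poses
  expect_equal(hyp$objective,
               pocketmolr:::hypothesis_objective(
                 hyp$selected_poses, attr(hyp, "fixed_poses")),
               tolerance = 1e-9)
})
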