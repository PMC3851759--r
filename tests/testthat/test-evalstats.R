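test_that("kendall tau matches the brute-force oracle, with ties", {
  kt <- kendall_tau(1:6, 1:6, n_perm = 99, seed = 1)
  expect_equal(kt$tau, 1.0)
  expect_equal(kendall_tau(1:6, 6:1, n_perm = 99, seed = 1)$tau, -1.0)
  # the worked tied example
  x <- c(3, 1, 4, 1, 5); y <- c(2, 7, 1, 8, 2)
  expect_equal(kendall_tau(x, y, n_perm = 99, seed = 1)$tau,
               r_kendall(x, y), tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(3:20, 1)
    a <- sample(1:8, n, replace = TRUE)
    b <- sample(1:8, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(kendall_tau(a, b, n_perm = 9, seed = 1)$tau,
                 r_kendall(a, b), tolerance = 1e-12)
  }
  expect_error(kendall_tau(rep(1, 5), 1:5), "constant")
})

test_that("permutation p-values are reproducible, bounded, calibrated", {
  set.seed(3)
  x <- rnorm(12); y <- x + rnorm(12, 0, 0.2)
  p1 <- kendall_tau(x, y, n_perm = 199, seed = 42)$p
  p2 <- kendall_tau(x, y, n_perm = 199, seed = 42)$p
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
  expect_lt(p1, 0.05)  # strong signal
  z <- rnorm(12)
  expect_gt(kendall_tau(x, z, n_perm = 199, seed = 42)$p, 0.01)
})

test_that("mean_abs_error basics", {
  expect_equal(mean_abs_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_abs_error(c(1, 2, 3) + 1, c(1, 2, 3)), 1)
  expect_equal(mean_abs_error(7.7, 7.2), 0.5)
  expect_error(mean_abs_error(numeric(0), numeric(0)), "empty")
})

test_that("pose RMSD: closed forms and brute-force agreement", {
  p <- pose(hexa_mol("r1"))
  expect_equal(pose_rmsd(p, p), 0)
  shifted <- pose(p$mol, sweep(p$coords, 2, c(1, 0, 0), "+"))
  expect_equal(pose_rmsd(p, shifted), 1.0, tolerance = 1e-12)
  set.seed(23)
  q <- pose(p$mol, p$coords + matrix(rnorm(nrow(p$coords) * 3), ncol = 3))
  hv <- which(!p$mol$atoms$is_hydrogen)
  brute <- sqrt(mean(rowSums((p$coords[hv, ] - q$coords[hv, ])^2)))
  expect_equal(pose_rmsd(p, q), brute, tolerance = 1e-12)
  other <- pose(chain_mol("r2"))
  expect_error(pose_rmsd(p, other), "mismatch")
})

test_that("contact partition reproduces hand-computed groups", {
  # 10 ligands at known positions; carbon-carbon surface distance is
  # center distance minus 3.4
  ligs <- lapply(1:10, function(k)
    pose(mk_mol(paste0("l", k), "C", c(k * 0.01, 0, 0))))
  pk <- mk_pocket("cp", rep("hydrophobic", 3),
                  c(3.5, 0, 0,     # surface < 0.2 for every ligand
                    0, 4.5, 0,     # surface ~1.1: touches none
                    3.995, 0, 0),  # surface 0.595 - 0.01k: ligand 10 only
                  cognate = ligs[[1]])
  cp <- contact_partition(list(pk), ligs)
  expect_equal(cp$participation, c(1, 0, 0.1))
  expect_equal(nrow(cp$high_group), 1)
  expect_equal(cp$high_group$x, 3.5)
  expect_equal(nrow(cp$low_group), 1)   # exactly 1/10 <= low_frac
  expect_equal(cp$low_group$x, 3.995)
})

test_that("contact partition pools the minimum over congruent variants", {
  lig <- pose(mk_mol("l", "C", c(0, 0, 0)))
  far <- mk_pocket("v1", "hydrophobic", c(6, 0, 0), cognate = lig)
  near <- mk_pocket("v2", "hydrophobic", c(3.6, 0, 0), cognate = lig)
  cp <- contact_partition(list(far, near), list(lig))
  expect_equal(cp$participation, 1)  # min over variants is in contact
})

test_that("nearest matching-probe distances follow the class rule", {
  pm <- pocketmol(rbind(
    mk_probes("steric", c(0, 0, 0)),
    mk_probes("donor", c(5, 0, 0), dir = c(1, 0, 0)),
    mk_probes("acceptor", c(0, 5, 0), dir = c(0, 1, 0))))
  atoms <- data.frame(
    interaction_class = c("hydrophobic", "donor", "acceptor",
                          "donor_acceptor", "neutral"),
    x = c(0, 5.5, 1, 1, 0), y = c(0, 0, 5, 0, 0), z = c(0, 0, 0, 0, 0))
  d <- nearest_probe_distance(atoms, pm)
  expect_equal(d[1], 0)                      # coincident steric
  expect_equal(d[2], 0.5)                    # donor atom vs donor probe
  expect_equal(d[3], 1.0)                    # acceptor vs acceptor probe
  expect_equal(d[4], 4.0)                    # donor_acceptor: nearer polar
  expect_equal(d[5], Inf)                    # neutral matches nothing
  # brute-force agreement on random sets
  set.seed(9)
  atoms2 <- data.frame(interaction_class = sample(c("hydrophobic", "donor",
                                                    "acceptor"), 5,
                                                  replace = TRUE),
                       x = rnorm(5), y = rnorm(5), z = rnorm(5))
  d2 <- nearest_probe_distance(atoms2, pm)
  match_types <- list(hydrophobic = "steric", donor = "donor",
                      acceptor = "acceptor")
  for (i in 1:5) {
    sel <- pm$probes$type %in% match_types[[atoms2$interaction_class[i]]]
    ref <- min(sqrt((pm$probes$x[sel] - atoms2$x[i])^2 +
                      (pm$probes$y[sel] - atoms2$y[i])^2 +
                      (pm$probes$z[sel] - atoms2$z[i])^2))
    expect_equal(d2[i], ref)
  }
})

test_that("two-sample KS matches hand-enumerated ECDF gaps", {
  expect_equal(ks_two_sample(1:5, 1:5)$D, 0)
  expect_equal(ks_two_sample(1:5, 11:15)$D, 1)
  x <- c(1, 2, 3); y <- c(1.5, 2.5)
  # ECDF gap enumeration: evaluate at all pooled points
  pts <- sort(c(x, y))
  gap <- max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
  expect_equal(ks_two_sample(x, y)$D, gap)
  r <- ks_two_sample(rnorm(50), rnorm(50, 5))
  expect_lt(r$p, 1e-6)
})
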