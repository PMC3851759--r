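test_that("tessellation places complementary probes at ideal geometry", {
  # single hydrophobic atom: steric probes at contact distance
  atom <- pose(mk_mol("c1", "C", c(0, 0, 0)))
  pool <- tessellate(list(atom), tessellation_config(fine_opt = FALSE))
  expect_true(all(pool$probes$type == "steric"))
  d <- sqrt(pool$probes$x^2 + pool$probes$y^2 + pool$probes$z^2)
  expect_true(all(abs(d - 3.4) < 0.05))
  # single acceptor atom: donor probes only, pointing at the atom
  acc <- pose(mk_mol("o1", c("C", "O"), c(0, 0, 0, 1.5, 0, 0),
                     rbind(c(1, 2, 2))))
  pool2 <- tessellate(list(acc), tessellation_config(fine_opt = FALSE))
  near_o <- sqrt((pool2$probes$x - 1.5)^2 + pool2$probes$y^2 +
                   pool2$probes$z^2) < 3.2
  expect_true(all(pool2$probes$type[near_o] %in% c("donor", "steric")))
  expect_true(any(pool2$probes$type == "donor"))
  don <- pool2$probes[pool2$probes$type == "donor", ]
  # directions are unit vectors aimed at the parent atom
  v <- cbind(1.5 - don$x, -don$y, -don$z)
  v <- v / sqrt(rowSums(v^2))
  expect_equal(v, as.matrix(don[, c("dx", "dy", "dz")]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("tessellation deduplicates and filters by minimum interaction", {
  p <- pose(hexa_mol("dd"))
  one <- tessellate(list(p), tessellation_config(fine_opt = FALSE))
  two <- tessellate(list(p, p), tessellation_config(fine_opt = FALSE))
  expect_equal(nrow(two$probes), nrow(one$probes))
  expect_true(all(one$score >= 0.02))
  # same-type dedupe radius respected
  for (ty in unique(one$probes$type)) {
    sub <- one$probes[one$probes$type == ty, ]
    if (nrow(sub) < 2) next
    dm <- as.matrix(dist(sub[, c("x", "y", "z")]))
    expect_gte(min(dm[upper.tri(dm)]), 0.5)
  }
  expect_error(tessellate(list()), "no active poses")
})

test_that("probe filter applies exact distance thresholds per class", {
  pk <- mk_pocket("f1", c("hydrophobic", "donor", "acceptor"),
                  c(0, 0, 0, 10, 0, 0, 20, 0, 0),
                  cognate = pose(mk_mol("cg", "C", c(0, 0, 0))))
  probes <- rbind(
    mk_probes("steric", c(0.9, 0, 0)),    # 0.9 from hydrophobic: keep
    mk_probes("steric", c(1.1, 0, 0)),    # 1.1: remove
    mk_probes("donor", c(11.8, 0, 0), dir = c(1, 0, 0)),   # 1.8: keep
    mk_probes("donor", c(12.2, 0, 0), dir = c(1, 0, 0)),   # 2.2: remove
    mk_probes("acceptor", c(21.9, 0, 0), dir = c(1, 0, 0)),# 1.9: keep
    mk_probes("donor", c(20.5, 0, 0), dir = c(1, 0, 0)))   # wrong class
  pool <- probe_pool(probes, as.character(1:6))
  f <- filter_probes(pool, list(pk))
  expect_true(f$filtered)
  expect_equal(f$source_pose_ids, c("1", "3", "5"))
})

test_that("filtering is an OR over variants, monotone, idempotent", {
  cg <- pose(mk_mol("cg", "C", c(0, 0, 0)))
  v1 <- mk_pocket("v1", "donor", c(50, 0, 0), cognate = cg)
  v2 <- mk_pocket("v2", "donor", c(0.5, 0, 0), cognate = cg)
  probes <- mk_probes("donor", c(2.0, 0, 0), dir = c(1, 0, 0))
  pool <- probe_pool(probes, "p")
  # retained through variant 2 only
  expect_equal(nrow(filter_probes(pool, list(v1))$probes), 0)
  expect_equal(nrow(filter_probes(pool, list(v1, v2))$probes), 1)
  # monotone: dropping a variant never adds probes
  p <- pose(hexa_mol("mono"))
  big <- tessellate(list(p), tessellation_config(fine_opt = FALSE))
  pk1 <- mk_pocket("m1", rep(c("hydrophobic", "donor", "acceptor"), 3),
                   as.vector(t(pocketmolr:::fibonacci_sphere(9, 5))),
                   cognate = cg)
  pk2 <- mk_pocket("m2", rep(c("donor_acceptor", "hydrophobic"), 3),
                   as.vector(t(pocketmolr:::fibonacci_sphere(6, 6))),
                   cognate = cg)
  f12 <- filter_probes(big, list(pk1, pk2))
  f1 <- filter_probes(big, list(pk1))
  expect_true(nrow(f1$probes) <= nrow(f12$probes))
  # idempotent
  f12b <- filter_probes(f12, list(pk1, pk2))
  expect_equal(f12b$probes, f12$probes)
  expect_error(filter_probes(big, list()), "empty pocket list")
})

test_that("a filter whose atoms coincide with every probe passes all", {
  p <- pose(hexa_mol("all"))
  pool <- tessellate(list(p), tessellation_config(fine_opt = FALSE))
  cls <- c(steric = "hydrophobic", donor = "donor",
           acceptor = "acceptor")[pool$probes$type]
  pk <- mk_pocket("coin", unname(cls),
                  as.vector(t(as.matrix(pool$probes[, c("x", "y", "z")]))),
                  cognate = pose(mk_mol("cg", "C", c(0, 0, 0))))
  f <- filter_probes(pool, list(pk))
  expect_equal(nrow(f$probes), nrow(pool$probes))
})

test_that("every non-neutral pose atom has a complementary candidate", {
  p <- pose(hexa_mol("cov"))
  pool <- tessellate(list(p), tessellation_config(fine_opt = FALSE))
  hv <- which(!p$mol$atoms$is_hydrogen)
  cls <- p$mol$atoms$interaction_class[hv]
  comp <- list(hydrophobic = "steric", donor = "acceptor",
               acceptor = "donor",
               donor_acceptor = c("donor", "acceptor"))
  for (i in seq_along(hv)) {
    if (cls[i] == "neutral") next
    d <- sqrt((pool$probes$x - p$coords[hv[i], 1])^2 +
                (pool$probes$y - p$coords[hv[i], 2])^2 +
                (pool$probes$z - p$coords[hv[i], 3])^2)
    near <- d < 3.6 & pool$probes$type %in% comp[[cls[i]]]
    expect_true(any(near), label = paste("atom", i, cls[i]))
  }
})

test_that("pool_stats counts are consistent", {
  p <- pose(hexa_mol("ps"))
  pool <- tessellate(list(p), tessellation_config(fine_opt = FALSE))
  st <- pool_stats(pool)
  expect_equal(sum(st$counts), st$total)
  expect_equal(st$total, nrow(pool$probes))
  empty <- probe_pool(pool$probes[0, ], character(0))
  st0 <- pool_stats(empty)
  expect_equal(sum(st0$counts), 0)
})
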