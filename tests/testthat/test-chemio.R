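test_that("interaction class rule table covers the canonical cases", {
  # carbonyl-like O (no H), amine N-H, aliphatic C, hydroxyl O, halogen
  mol <- mk_mol("rules", c("C", "C", "O", "N", "H", "O", "H", "Cl", "S"),
                c(0, 0, 0,  1.5, 0, 0,  2.1, 1.2, 0,  -1.2, 0.8, 0,
                  -1.2, 1.9, 0,  1.6, -1.4, 0,  2.4, -1.9, 0,
                  -0.7, -1.3, 0,  3.0, 0.2, 0),
                rbind(c(1, 2, 1), c(2, 3, 2), c(1, 4, 1), c(4, 5, 1),
                      c(2, 6, 1), c(6, 7, 1), c(1, 8, 1), c(2, 9, 1)))
  cls <- mol$atoms$interaction_class
  expect_equal(cls[3], "acceptor")        # carbonyl O
  expect_equal(cls[4], "donor")           # N with H
  expect_equal(cls[6], "donor_acceptor")  # hydroxyl O
  expect_equal(cls[8], "hydrophobic")     # halogen
  expect_equal(cls[9], "hydrophobic")     # thioether-like S (C/S/H only)
  expect_equal(cls[5], "neutral")         # hydrogen
  # C1 bonded to C,N,Cl -> not pure C/H/S -> neutral
  expect_equal(cls[1], "neutral")
  # idempotence
  expect_identical(assign_interaction_classes(mol)$atoms, mol$atoms)
})

test_that("aliphatic carbons are hydrophobic; unknown elements warn", {
  mol <- mk_mol("alk", c("C", "C", "H"),
                c(0, 0, 0, 1.5, 0, 0, 2.1, 0.9, 0),
                rbind(c(1, 2, 1), c(2, 3, 1)))
  expect_true(all(mol$atoms$interaction_class[1:2] == "hydrophobic"))
  # both the radius lookup and the typing warn on an unknown element
  expect_warning(expect_warning(molecule("xx", c("Xx"), matrix(0, 1, 3)),
                                "unknown element"), "unknown element")
})

test_that("activity_to_pki handles units, identities, and errors", {
  expect_equal(activity_to_pki(1, "nM"), 9.0)
  expect_equal(activity_to_pki(1, "M"), 0.0)
  expect_equal(activity_to_pki(10, "uM"), 5.0)
  expect_equal(activity_to_pki(7.3, "pKi"), 7.3)
  expect_error(activity_to_pki(-1, "nM"), "positive")
  expect_error(activity_to_pki(0, "uM"), "positive")
  # strictly decreasing in concentration; inverse identity
  x <- c(0.5, 1, 20, 300)
  p <- activity_to_pki(x, "uM")
  expect_true(all(diff(p) < 0))
  expect_equal(10^(-p) / 1e-6, x, tolerance = 1e-9)
})

test_that("conformer generation is capped, diverse, deterministic", {
  rigid <- hexa_mol()
  rigid$rotatable_bonds <- integer(0)
  r1 <- generate_conformers(rigid, max_n = 5, seed = 3)
  expect_length(r1$conformers, 1)

  flex <- chain_mol()
  expect_gt(length(flex$rotatable_bonds), 0)
  f1 <- generate_conformers(flex, max_n = 5, seed = 3)
  expect_true(length(f1$conformers) >= 2 && length(f1$conformers) <= 5)
  f2 <- generate_conformers(flex, max_n = 5, seed = 3)
  expect_identical(f1$conformers, f2$conformers)
  # pairwise diversity after superposition
  hv <- which(!f1$atoms$is_hydrogen)
  for (i in seq_along(f1$conformers)[-1]) {
    for (j in seq_len(i - 1)) {
      expect_gte(pocketmolr:::rmsd_superposed(
        f1$conformers[[i]][hv, ], f1$conformers[[j]][hv, ]), 0.5)
    }
  }
  # clash filter: no nonbonded heavy pair below 70% of radii sum
  for (cc in f1$conformers)
    expect_false(pocketmolr:::has_internal_clash(f1, cc))
})

test_that("SDF round-trip preserves structure and data", {
  mols <- list(hexa_mol("m1"), chain_mol("m2"), hexa_mol("m3"))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(mols, path, tags = list(pki = c(7.1, 6.2, 5.5)))
  back <- read_molecules(path, "sdf")
  expect_length(back, 3)
  for (k in 1:3) {
    expect_equal(back[[k]]$id, mols[[k]]$id)
    expect_equal(back[[k]]$atoms$element, mols[[k]]$atoms$element)
    expect_equal(back[[k]]$conformers[[1]], mols[[k]]$conformers[[1]],
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(nrow(back[[k]]$bonds), nrow(mols[[k]]$bonds))
  }
})

test_that("MOL2 round-trip preserves structure", {
  mols <- list(hexa_mol("m1"), chain_mol("m2"))
  path <- withr::local_tempfile(fileext = ".mol2")
  write_molecules(mols, path, format = "mol2")
  back <- read_molecules(path, "mol2")
  expect_length(back, 2)
  for (k in 1:2) {
    expect_equal(back[[k]]$atoms$element, mols[[k]]$atoms$element)
    expect_equal(back[[k]]$conformers[[1]], mols[[k]]$conformers[[1]],
                 tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("2D records (all-zero z) are rejected", {
  flat <- mk_mol("flat", c("C", "C", "C"),
                 c(0, 0, 0, 1.5, 0, 0, 2.2, 1.2, 0))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_molecules(flat, path)
  expect_error(read_molecules(path, "sdf"), "no 3D coordinates")
})

test_that("pocket reading applies the cutoff and typing rules", {
  pk <- mk_pocket("toy", rep(c("hydrophobic", "donor", "acceptor"), 4),
                  as.vector(t(cbind(seq(0.5, 6, length.out = 12), 0, 4))))
  td <- withr::local_tempdir()
  pdb <- file.path(td, "toy.pdb")
  pocketmolr:::write_pocket_pdb(pk, pdb)
  lig <- file.path(td, "lig.sdf")
  write_molecules(pk$cognate_ligand, lig)
  # generous cutoff keeps everything
  p1 <- read_pocket(pdb, lig, pocket_cutoff = 50)
  expect_equal(nrow(p1$atoms), 12)
  expect_equal(p1$atoms$interaction_class, pk$atoms$interaction_class)
  # tight cutoff drops far atoms but keeps near ones
  p2 <- read_pocket(pdb, lig, pocket_cutoff = 4.5)
  expect_lt(nrow(p2$atoms), 12)
  # degenerate cutoff -> empty pocket error
  expect_error(read_pocket(pdb, lig, pocket_cutoff = 0.1), "empty pocket")
  expect_error(read_pocket(pdb, "ZZZ", pocket_cutoff = 5), "not found")
})

test_that("threshold semantics: atom just outside the cutoff is excluded", {
  lig <- mk_mol("l", "C", c(0, 0, 0))
  pk <- mk_pocket("t2", c("hydrophobic", "hydrophobic"),
                  c(5.9, 0, 0, 6.5, 0, 0), cognate = pose(lig))
  td <- withr::local_tempdir()
  pdb <- file.path(td, "t2.pdb")
  pocketmolr:::write_pocket_pdb(pk, pdb)
  ligf <- file.path(td, "l.sdf")
  write_molecules(lig, ligf)
  p <- read_pocket(pdb, ligf, pocket_cutoff = 6)
  expect_equal(nrow(p$atoms), 1)
  expect_equal(p$atoms$x, 5.9)
})

test_that("pocketmol text format round-trips", {
  pm <- pocketmol(rbind(
    mk_probes("steric", c(1.2345, -2, 0.5)),
    mk_probes("donor", c(0, 1, 2), dir = c(0, 0, 1)),
    mk_probes("acceptor", c(3, -1, 0), dir = c(1, 0, 0))),
    provenance = "structure_guided", density_label = "50")
  path <- withr::local_tempfile(fileext = ".pocketmol")
  write_pocketmol(pm, path)
  back <- read_pocketmol(path)
  expect_equal(back$provenance, "structure_guided")
  expect_equal(back$density_label, "50")
  expect_equal(back$probes$type, pm$probes$type)
  expect_equal(back$probes$x, pm$probes$x, tolerance = 1e-3)
  expect_true(all(is.na(back$probes$dx[back$probes$type == "steric"])))
  expect_equal(back$probes$dz[2], 1)
})
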