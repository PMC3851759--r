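# Seeded synthetic benchmark generator: pocket ensembles, congeneric and
# diverse bead-ligand series with reference poses, and activities drawn
# from a ground-truth pocketmol under the max-pose scoring rule.
#
# Bead chemistry: atoms restricted to C/N/O(/H), bonds of fixed 1.5 A
# length, zig-zag or template geometry. The method's math needs only typed
# points and bonds, not real chemistry; every typing and scoring path is
# exercised.

## ---- bead molecule helpers ------------------------------------------------

# Zig-zag backbone coordinates (bond 1.5 A, ~112 degree angles) with a
# small alternating out-of-plane pucker so bead molecules are genuinely
# 3D (flat geometries are rejected on read and leave reflections
# ambiguous).
zigzag_coords <- function(n, bond = 1.5) {
  half <- 34 * pi / 180
  dx <- bond * cos(half); dy <- bond * sin(half)
  i <- seq_len(n)
  cbind(x = (i - 1) * dx,
        y = ifelse(i %% 2 == 0, dy, 0),
        z = 0.14 * ifelse(i %% 3 == 0, 1, ifelse(i %% 3 == 1, -1, 0.25)))
}

# Assemble a bead molecule; hydrogens are added to the heavy atoms listed
# in `h_on`, pointing away from their bonded neighbors.
bead_mol <- function(id, el, coords, bonds, h_on = integer(0)) {
  coords <- as.matrix(coords)
  el <- as.character(el)
  bonds <- matrix(as.integer(bonds), ncol = 3)
  for (a in h_on) {
    nbrs <- c(bonds[bonds[, 1] == a, 2], bonds[bonds[, 2] == a, 1])
    dir <- if (length(nbrs)) {
      v <- coords[a, ] - colMeans(coords[nbrs, , drop = FALSE])
      n <- sqrt(sum(v^2))
      if (n < 1e-6) c(0, 0, 1) else v / n
    } else c(0, 0, 1)
    coords <- rbind(coords, coords[a, ] + dir * 1.0)
    el <- c(el, "H")
    bonds <- rbind(bonds, c(a, length(el), 1L))
  }
  molecule(id, el, coords, bonds)
}

# Substituent catalogue for decoration sites. Each entry adds atoms at
# site + k * 1.5 * dir and returns the updated building blocks.
SUBSTITUENTS <- c("none", "me", "oh", "nh", "keto", "et")

apply_substituent <- function(parts, site_atom, dir, kind) {
  if (kind == "none") return(parts)
  p0 <- parts$coords[site_atom, ]
  add <- function(parts, el, pos, parent, h = FALSE) {
    parts$coords <- rbind(parts$coords, pos)
    parts$el <- c(parts$el, el)
    idx <- length(parts$el)
    parts$bonds <- rbind(parts$bonds, c(parent, idx, 1L))
    if (h) parts$h_on <- c(parts$h_on, idx)
    parts
  }
  switch(kind,
    me = add(parts, "C", p0 + 1.5 * dir, site_atom),
    oh = add(parts, "O", p0 + 1.5 * dir, site_atom, h = TRUE),
    nh = add(parts, "N", p0 + 1.5 * dir, site_atom, h = TRUE),
    keto = add(parts, "O", p0 + 1.5 * dir, site_atom),
    et = {
      parts <- add(parts, "C", p0 + 1.5 * dir, site_atom)
      add(parts, "C", p0 + 3.0 * dir, length(parts$el))
    })
}

# Congeneric scaffold: 6-bead zig-zag C-C-C-C-N(H)-O with three
# perpendicular decoration sites (two hydrophobic carbons, one donor N,
# one terminal acceptor O).
congeneric_scaffold <- function() {
  xy <- zigzag_coords(6)
  list(el = c("C", "C", "C", "C", "N", "O"), coords = xy,
       bonds = cbind(1:5, 2:6, 1L), h_on = 5L,
       sites = list(list(at = 2L, dir = c(0, 1, 0)),
                    list(at = 3L, dir = c(0, -1, 0)),
                    list(at = 1L, dir = c(0, -1, 0))))
}

# Five structurally distinct diverse scaffolds (ring, star, chains).
diverse_scaffolds <- function() {
  ring <- {
    th <- 2 * pi * (0:4) / 5
    r <- 1.5 / (2 * sin(pi / 5))
    list(el = c("O", "C", "O", "C", "N"),
         coords = cbind(r * cos(th), r * sin(th),
                        0.12 * c(1, -1, 1, -1, 0.3)),
         bonds = cbind(1:5, c(2:5, 1L), 1L), h_on = integer(0),
         sites = list(list(at = 1L, dir = c(cos(th[1]), sin(th[1]), 0)),
                      list(at = 3L, dir = c(cos(th[3]), sin(th[3]), 0))))
  }
  star <- {
    dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                  c(-1, -1, 1)) / sqrt(3)
    list(el = c("N", "C", "O", "C", "C"),
         coords = rbind(c(0, 0, 0), 1.5 * dirs),
         bonds = cbind(1L, 2:5, 1L), h_on = integer(0),
         sites = list(list(at = 4L, dir = dirs[3, ]),
                      list(at = 5L, dir = dirs[4, ])))
  }
  chain7 <- {
    xy <- zigzag_coords(7)
    list(el = c("C", "C", "C", "O", "C", "N", "O"), coords = xy,
         bonds = cbind(1:6, 2:7, 1L), h_on = 6L,
         sites = list(list(at = 3L, dir = c(0, -1, 0)),
                      list(at = 5L, dir = c(0, -1, 0))))
  }
  ell <- {
    xy <- zigzag_coords(4)
    xy <- rbind(xy, xy[2, ] + c(0, 1.5, 0), xy[2, ] + c(0, 3.0, 0))
    list(el = c("C", "C", "O", "C", "N", "C"), coords = xy,
         bonds = rbind(cbind(1:3, 2:4, 1L), c(2, 5, 1L), c(5, 6, 1L)),
         h_on = 5L,
         sites = list(list(at = 4L, dir = c(0, 1, 0)),
                      list(at = 6L, dir = c(0, 1, 0))))
  }
  tee <- {
    xy <- zigzag_coords(5)
    xy <- rbind(xy, xy[3, ] + c(0, -1.5, 0), xy[3, ] + c(0, -3.0, 0))
    list(el = c("O", "C", "O", "C", "N", "C", "O"), coords = xy,
         bonds = rbind(cbind(1:4, 2:5, 1L), c(3, 6, 1L), c(6, 7, 1L)),
         h_on = 5L,
         sites = list(list(at = 1L, dir = c(0, 1, 0)),
                      list(at = 7L, dir = c(0, -1, 0))))
  }
  list(ring = ring, star = star, chain7 = chain7, ell = ell, tee = tee)
}

build_decorated <- function(id, scaffold, kinds) {
  parts <- scaffold
  for (k in seq_along(scaffold$sites)) {
    kind <- if (k <= length(kinds)) kinds[k] else "none"
    s <- scaffold$sites[[k]]
    parts <- apply_substituent(parts, s$at, s$dir, kind)
  }
  bead_mol(id, parts$el, parts$coords, parts$bonds, parts$h_on)
}

# Center heavy atoms at the origin (all conformers moved by the same shift).
center_molecule <- function(mol) {
  hv <- heavy_idx(mol)
  shift <- colMeans(mol$conformers[[1]][hv, , drop = FALSE])
  mol$conformers <- lapply(mol$conformers, function(cc)
    sweep(cc, 2, shift))
  mol
}

## ---- pocket ensemble ------------------------------------------------------

# Evenly distributed points on a sphere (Fibonacci lattice).
fibonacci_sphere <- function(n, radius = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# The cognate bead ligand: a fully decorated member of the congeneric
# chemotype, so the wall tessellated around it hugs the envelope the
# whole series occupies (as a co-crystallized active would).
cognate_template <- function(id) {
  scaf <- congeneric_scaffold()
  parts <- scaf
  kinds <- c("et", "keto", "me")  # asymmetric arms: flip-distinguishable
  for (k in seq_along(scaf$sites)) {
    s <- scaf$sites[[k]]
    parts <- apply_substituent(parts, s$at, s$dir, kinds[k])
  }
  mol <- bead_mol(id, parts$el, parts$coords, parts$bonds, parts$h_on)
  hv <- heavy_idx(mol)
  shift <- colMeans(mol$conformers[[1]][hv, , drop = FALSE])
  mol$conformers[[1]] <- sweep(mol$conformers[[1]], 2, shift)
  mol
}

#' Generate a synthetic pocket ensemble
#'
#' The base pocket wall is built complementary to the cognate bead ligand:
#' the cognate pose is tessellated and each probe position becomes a typed
#' wall pseudo-atom (steric probe positions become hydrophobic carbons,
#' donor probe positions donor nitrogens, acceptor probe positions
#' acceptor oxygens, with a seeded fraction of oxygens re-typed
#' donor_acceptor). This yields a snug concave shell at ligand-contact
#' distance, the geometry the probe filter assumes of a real binding
#' site. Variants apply per-atom Gaussian jitter of `jitter_sd` to wall
#' and cognate coordinates, preserving the typing. Deterministic given
#' `seed`.
#'
#' @param seed integer seed.
#' @param n_variants number of jittered variants (default 5).
#' @param jitter_sd per-coordinate jitter (Angstrom, default 0.25).
#' @param wall_spacing wall atom spacing (tessellation dedupe radius,
#'   Angstrom, default 0.7).
#' @return list(base, variants): `pm_pocket` objects.
#' @export
make_pocket_ensemble <- function(seed, n_variants = 5, jitter_sd = 0.25,
                                 wall_spacing = 0.7) {
  stopifnot(n_variants >= 1)
  with_seed(seed, {
    base_cog <- cognate_template("cognate_base")
    cpose <- pose(base_cog, provenance = "crystal")
    tcfg <- tessellation_config(min_probe_score = -1e9, fine_opt = FALSE,
                                dedupe_radius = wall_spacing)
    wall <- tessellate(list(cpose), tcfg)$probes
    # push the wall slightly beyond ideal contact so series ligands that
    # stay within the cognate envelope cannot clash with it
    chv <- pose_heavy_coords(cpose)
    for (i in seq_len(nrow(wall))) {
      p <- c(wall$x[i], wall$y[i], wall$z[i])
      d <- sqrt(colSums((t(chv) - p)^2))
      u <- (p - chv[which.min(d), ]) / max(min(d), 1e-9)
      p <- p + 0.5 * u
      wall$x[i] <- p[1]; wall$y[i] <- p[2]; wall$z[i] <- p[3]
    }
    cls <- c(steric = "hydrophobic", donor = "donor",
             acceptor = "acceptor")[wall$type]
    # a seeded quarter of the acceptor oxygens double as donors (hydroxyl)
    accs <- which(cls == "acceptor")
    da <- accs[stats::runif(length(accs)) < 0.25]
    cls[da] <- "donor_acceptor"
    el <- c(hydrophobic = "C", donor = "N", acceptor = "O",
            donor_acceptor = "O")[cls]
    atoms <- data.frame(element = unname(el),
                        interaction_class = unname(cls),
                        vdw_radius = vdw_radius(el),
                        is_hydrogen = FALSE,
                        x = wall$x, y = wall$y, z = wall$z,
                        stringsAsFactors = FALSE)
    base <- protein_pocket("pocket_base", atoms, cpose)
    variants <- lapply(seq_len(n_variants), function(v) {
      a <- atoms
      a$x <- a$x + stats::rnorm(nrow(a), 0, jitter_sd)
      a$y <- a$y + stats::rnorm(nrow(a), 0, jitter_sd)
      a$z <- a$z + stats::rnorm(nrow(a), 0, jitter_sd)
      cog <- cognate_template(sprintf("cognate_v%d", v))
      cc <- cog$conformers[[1]]
      cc <- cc + matrix(stats::rnorm(length(cc), 0, jitter_sd / 2),
                        nrow(cc), 3)
      cog$conformers[[1]] <- cc
      protein_pocket(sprintf("pocket_v%d", v), a,
                     pose(cog, cc, provenance = "crystal"))
    })
    list(base = base, variants = variants)
  })
}

## ---- ligand series --------------------------------------------------------

ligand_clash_free <- function(mol, coords, pocket, frac = 0.7) {
  hv <- heavy_idx(mol)
  lx <- coords[hv, , drop = FALSE]
  lr <- mol$atoms$vdw_radius[hv]
  pa <- pocket$atoms[!pocket$atoms$is_hydrogen, , drop = FALSE]
  px <- t(as.matrix(pa[, c("x", "y", "z")]))
  for (i in seq_len(nrow(lx))) {
    d <- sqrt(colSums((px - lx[i, ])^2))
    if (any(d < frac * (lr[i] + pa$vdw_radius))) return(FALSE)
  }
  !has_internal_clash(mol, coords)
}

#' Generate congeneric and diverse bead-ligand series with reference poses
#'
#' The congeneric series shares one zig-zag scaffold with enumerated
#' substituent variations at three sites; the diverse series cycles five
#' structurally distinct scaffolds (ring, star, chains) with varied
#' decorations and seeded placement orientations. All reference poses are
#' clash-free inside `pocket`; molecules are asymmetric so frame-fixed
#' RMSD is well defined. Each molecule's stored conformer is the reference
#' geometry moved to a canonical centered frame (placement is not leaked).
#'
#' @param seed integer seed.
#' @param n_congeneric,n_diverse series sizes.
#' @param pocket the base `pm_pocket` the poses must fit.
#' @return list(congeneric, diverse): lists of list(mol, ref_pose).
#' @export
make_ligand_series <- function(seed, n_congeneric, n_diverse, pocket) {
  with_seed(seed, {
    scaf <- congeneric_scaffold()
    combos <- expand.grid(a = SUBSTITUENTS, b = SUBSTITUENTS,
                          c = SUBSTITUENTS, stringsAsFactors = FALSE)
    combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
    if (n_congeneric > nrow(combos))
      stop("requested more congeneric molecules than substituent combos")
    congeneric <- list()
    ci <- 0
    for (r in seq_len(nrow(combos))) {
      if (length(congeneric) >= n_congeneric) break
      ci <- ci + 1
      id <- sprintf("cong_%03d", ci)
      mol <- build_decorated(id, scaf, unlist(combos[r, ]))
      ref <- sweep(mol$conformers[[1]], 2,
                   colMeans(mol$conformers[[1]][heavy_idx(mol), ,
                                                drop = FALSE]))
      if (!ligand_clash_free(mol, ref, pocket)) next
      mol$conformers[[1]] <- ref
      congeneric[[length(congeneric) + 1L]] <-
        list(mol = center_molecule(mol),
             ref_pose = pose(mol, ref, "crystal"))
    }
    if (length(congeneric) < n_congeneric)
      stop("cavity too small for the requested congeneric series")

    scafs <- diverse_scaffolds()
    deco <- c("none", "me", "oh", "nh", "keto")
    diverse <- list()
    di <- 0
    while (length(diverse) < n_diverse && di < 10 * n_diverse) {
      di <- di + 1
      sc <- scafs[[((di - 1) %% length(scafs)) + 1]]
      kinds <- sample(deco, length(sc$sites), replace = TRUE)
      id <- sprintf("div_%02d", di)
      mol <- build_decorated(id, sc, kinds)
      # seeded placement: rotate about z, small tilt, centered
      ang <- c(stats::runif(1, -0.3, 0.3), stats::runif(1, -0.3, 0.3),
               stats::runif(1, 0, 2 * pi))
      cc <- mol$conformers[[1]]
      cc <- sweep(cc, 2, colMeans(cc[heavy_idx(mol), , drop = FALSE]))
      ref <- cc %*% t(rot_xyz(ang))
      if (!ligand_clash_free(mol, ref, pocket)) next
      mol$conformers[[1]] <- ref
      diverse[[length(diverse) + 1L]] <-
        list(mol = center_molecule(mol), ref_pose = pose(mol, ref, "crystal"))
    }
    if (length(diverse) < n_diverse)
      stop("cavity too small for the requested diverse series")
    list(congeneric = congeneric, diverse = diverse)
  })
}

## ---- ground truth & activities --------------------------------------------

# Ground-truth pocketmol: tessellate a spread of reference poses, filter
# against the pocket ensemble, then thin to `size` probes with a minimum
# spacing, best tessellation scores first.
make_ground_truth <- function(series, pockets, size = 40, seed = 1,
                              params = score_params()) {
  cong <- series$congeneric
  div <- series$diverse
  pick <- unique(c(1L, ceiling(length(cong) / 2), length(cong)))
  seeds_poses <- c(lapply(cong[pick], `[[`, "ref_pose"),
                   lapply(div[seq_len(min(2, length(div)))], `[[`,
                          "ref_pose"))
  pool <- tessellate(seeds_poses, tessellation_config(), params)
  pool <- filter_probes(pool, pockets)
  pr <- pool$probes
  sc <- pool$score
  ord <- order(-sc)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) >= size) break
    if (length(keep)) {
      d2 <- (pr$x[keep] - pr$x[i])^2 + (pr$y[keep] - pr$y[i])^2 +
        (pr$z[keep] - pr$z[i])^2
      if (min(d2) < 1.0) next
    }
    keep <- c(keep, i)
  }
  pocketmol(pr[sort(keep), , drop = FALSE], provenance = "ground_truth",
            density_label = as.character(length(keep)))
}

#' Simulate activities from a ground-truth pocketmol
#'
#' pKi = clip(score_pose(reference, gt)$total + N(0, noise_sd), lo, hi),
#' seeded - the max-pose rule's generative counterpart (reference poses
#' are locally optimal in the ground-truth model by construction in
#' [make_benchmark()]).
#'
#' @param gt ground-truth `pm_pocketmol`.
#' @param entries list of list(mol, ref_pose).
#' @param noise_sd Gaussian noise SD (pKd).
#' @param pki_range clip range (default c(0, 12)).
#' @param seed integer seed.
#' @param params scoring parameters.
#' @return data frame: molecule_id, pki, true_score, assay_type.
#' @export
simulate_activities <- function(gt, entries, noise_sd, pki_range = c(0, 12),
                                seed = 1, params = score_params()) {
  stopifnot(nrow(gt$probes) > 0)
  with_seed(seed, {
    sc <- vapply(entries, function(e)
      score_pose(e$ref_pose, gt, params)$total, numeric(1))
    pki <- pmin(pmax(sc + stats::rnorm(length(sc), 0, noise_sd),
                     pki_range[1]), pki_range[2])
    data.frame(molecule_id = vapply(entries, function(e) e$mol$id,
                                    character(1)),
               pki = pki, true_score = sc, assay_type = "synthetic",
               stringsAsFactors = FALSE)
  })
}

# Rigid local refinement of a pose against a pocketmol with a hard
# penalty for clashing into the pocket wall; returns NULL if no
# clash-free improvement is found.
refine_in_pocket <- function(p, pm, pocket, tether = 1.5,
                             params = score_params()) {
  hv <- heavy_idx(p$mol)
  lr <- p$mol$atoms$vdw_radius[hv]
  pa <- pocket$atoms[!pocket$atoms$is_hydrogen, , drop = FALSE]
  px <- t(as.matrix(pa[, c("x", "y", "z")]))
  clash_depth <- function(coords) {
    lx <- coords[hv, , drop = FALSE]
    worst <- 0
    for (i in seq_len(nrow(lx))) {
      d <- sqrt(colSums((px - lx[i, ])^2))
      worst <- max(worst, max(0.7 * (lr[i] + pa$vdw_radius) - d))
    }
    worst
  }
  prdf <- target_probes(pm, params)
  obj <- fit_objective(p$mol, prdf, params)
  f <- function(par) {
    if (sqrt(sum(par[4:6]^2)) > tether) return(1e9)
    cc <- apply_rigid(p$coords, par)
    -obj(cc) + 50 * clash_depth(cc)^2
  }
  opt <- stats::optim(rep(0, 6), f, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-8))
  cc <- apply_rigid(p$coords, opt$par)
  if (clash_depth(cc) > 1e-6) return(NULL)
  pose(p$mol, cc, "crystal", score = obj(cc))
}

#' Benchmark configuration
#'
#' Defaults mirror the shape of a lead-optimization study: 5 pocket
#' variants, 30 congeneric training ligands, 20 congeneric and 15 diverse
#' test ligands, 0.2 pKd assay noise.
#' @param n_variants,jitter_sd pocket ensemble settings.
#' @param n_train,n_congeneric_test,n_diverse series sizes.
#' @param noise_sd activity noise SD (pKd).
#' @param gt_size ground-truth probe count.
#' @param pki_range activity clip range.
#' @param pocket_cutoff shell cutoff recorded for pocket round-trips.
#' @export
benchmark_config <- function(n_variants = 5, jitter_sd = 0.25, n_train = 30,
                             n_congeneric_test = 20, n_diverse = 15,
                             noise_sd = 0.2, gt_size = 40,
                             pki_range = c(0, 12), pocket_cutoff = 7) {
  list(n_variants = n_variants, jitter_sd = jitter_sd, n_train = n_train,
       n_congeneric_test = n_congeneric_test, n_diverse = n_diverse,
       noise_sd = noise_sd, gt_size = gt_size, pki_range = pki_range,
       pocket_cutoff = pocket_cutoff)
}

#' Compose a full synthetic benchmark
#'
#' Generates the pocket ensemble, ligand series, and ground-truth
#' pocketmol; locally refines each reference pose in the ground-truth
#' model (rejecting any refinement that clashes with the base pocket) so
#' references are locally optimal; simulates activities; and splits the
#' congeneric series into train and held-out test sets. Bit-reproducible
#' given (seed, config). With `write_dir`, all files are written in the
#' standard formats so the file-driven pipeline runs on them unmodified.
#'
#' @param seed integer seed.
#' @param config a [benchmark_config()].
#' @param write_dir optional output directory.
#' @param params scoring parameters.
#' @return a `pm_benchmark`: pockets (base + variants), ground_truth,
#'   train / congeneric_test / diverse_test (lists of
#'   list(mol, pki, ref_pose)), activities (data frame), seed, config.
#' @export
make_benchmark <- function(seed, config = benchmark_config(),
                           write_dir = NULL, params = score_params()) {
  ens <- make_pocket_ensemble(seed, config$n_variants, config$jitter_sd)
  pockets <- c(list(ens$base), ens$variants)
  n_cong <- config$n_train + config$n_congeneric_test
  # surplus congeners: members whose global binding optimum deviates from
  # the shared series mode are discarded below, keeping labels both
  # max-pose-truthful and explainable by one alignment
  n_extra <- min(n_cong + 15, 200)
  series <- make_ligand_series(seed + 1, n_extra, config$n_diverse,
                               ens$base)
  gt <- make_ground_truth(series, pockets, size = config$gt_size,
                          seed = seed + 2, params = params)
  # Reference poses follow the max-pose generative rule, with the
  # search scoped to how each series binds: congeneric references keep
  # the coherent series placement (multi-start local polish around the
  # constructed pose), while each diverse reference is a global rigid
  # fit into the ground truth (distinct chemotypes bind in their own
  # orientations). Both are clash-constrained against the base wall.
  polish_local <- function(e, k) {
    best <- refine_in_pocket(e$ref_pose, gt, ens$base, params = params)
    starts <- with_seed(seed + 30 + k, lapply(seq_len(3), function(j)
      pose(e$mol, transform_coords(e$ref_pose$coords,
                                   stats::rnorm(3, 0, 0.15),
                                   stats::rnorm(3, 0, 0.4),
                                   colMeans(pose_heavy_coords(e$ref_pose))))))
    for (st in starts) {
      cand <- refine_in_pocket(st, gt, ens$base, params = params)
      if (!is.null(cand) && (is.null(best) || cand$score > best$score))
        best <- cand
    }
    if (!is.null(best) && best$score > score_pose(e$ref_pose, gt,
                                                  params)$total)
      e$ref_pose <- pose(e$mol, best$coords, "crystal")
    e
  }
  polish_global <- function(e, k) {
    cands <- fit_to_target(e$mol, gt, n_starts = 6, n_out = 3,
                           seed = seed + 40 + k, params = params)
    best <- NULL
    for (cand in c(cands, list(e$ref_pose))) {
      ref <- refine_in_pocket(cand, gt, ens$base, params = params)
      if (!is.null(ref) && (is.null(best) || ref$score > best$score))
        best <- ref
    }
    if (!is.null(best) && best$score > score_pose(e$ref_pose, gt,
                                                  params)$total)
      e$ref_pose <- pose(e$mol, best$coords, "crystal")
    e
  }
  series$congeneric <- lapply(seq_along(series$congeneric), function(k)
    polish_local(series$congeneric[[k]], k))
  # retain congeners whose coherent placement is also their global
  # optimum (within 0.5 pKd)
  coherent <- vapply(seq_along(series$congeneric), function(k) {
    e <- series$congeneric[[k]]
    local_sc <- score_pose(e$ref_pose, gt, params)$total
    g <- polish_global(e, 700 + k)
    score_pose(g$ref_pose, gt, params)$total <= local_sc + 0.5
  }, logical(1))
  series$congeneric <- series$congeneric[coherent]
  if (length(series$congeneric) < n_cong)
    stop("too few frame-coherent congeneric ligands; enlarge the series")
  series$congeneric <- series$congeneric[seq_len(n_cong)]
  series$diverse <- lapply(seq_along(series$diverse), function(k)
    polish_global(series$diverse[[k]], 500 + k))
  entries <- c(series$congeneric, series$diverse)
  acts <- simulate_activities(gt, entries, config$noise_sd,
                              config$pki_range, seed + 3, params)
  for (i in seq_along(entries)) entries[[i]]$pki <- acts$pki[i]
  ncg <- length(series$congeneric)
  cong <- entries[seq_len(ncg)]
  div <- entries[ncg + seq_len(length(series$diverse))]
  # The crystallographic frame is arbitrary: apply one seeded global
  # rigid transform to the whole complex (pockets, cognates, ground
  # truth, reference poses). Ligand input geometries stay canonical, so
  # the frame is only recoverable through the structures.
  tf <- with_seed(seed + 5, list(R = rot_xyz(stats::runif(3, 0, 2 * pi)),
                                 t = stats::runif(3, -3, 3)))
  move <- function(coords) sweep(coords %*% t(tf$R), 2, tf$t, "+")
  pockets <- lapply(pockets, function(pk) {
    xyz <- move(as.matrix(pk$atoms[, c("x", "y", "z")]))
    pk$atoms$x <- xyz[, 1]; pk$atoms$y <- xyz[, 2]; pk$atoms$z <- xyz[, 3]
    cog <- pk$cognate_ligand
    cog$coords <- move(cog$coords)
    cog$mol$conformers[[1]] <- cog$coords
    pk$cognate_ligand <- cog
    pk
  })
  pr <- gt$probes
  xyz <- move(as.matrix(pr[, c("x", "y", "z")]))
  pr$x <- xyz[, 1]; pr$y <- xyz[, 2]; pr$z <- xyz[, 3]
  pol <- pr$type != "steric"
  if (any(pol)) {
    d <- as.matrix(pr[pol, c("dx", "dy", "dz")]) %*% t(tf$R)
    pr$dx[pol] <- d[, 1]; pr$dy[pol] <- d[, 2]; pr$dz[pol] <- d[, 3]
  }
  gt <- pocketmol(pr, provenance = gt$provenance,
                  density_label = gt$density_label)
  entries <- lapply(entries, function(e) {
    e$ref_pose <- pose(e$mol, move(e$ref_pose$coords), "crystal")
    e
  })
  cong <- entries[seq_len(ncg)]
  div <- entries[ncg + seq_len(length(series$diverse))]
  train_idx <- with_seed(seed + 4, sort(sample.int(ncg, config$n_train)))
  bm <- structure(list(pockets = pockets, ground_truth = gt,
                       train = cong[train_idx],
                       congeneric_test = cong[-train_idx],
                       diverse_test = div, activities = acts,
                       seed = seed, config = config),
                  class = "pm_benchmark")
  if (!is.null(write_dir)) write_benchmark(bm, write_dir)
  bm
}

#' @export
print.pm_benchmark <- function(x, ...) {
  cat("<pm_benchmark> seed", x$seed, ":", length(x$pockets), "pockets,",
      length(x$train), "train /", length(x$congeneric_test),
      "congeneric test /", length(x$diverse_test), "diverse test;",
      nrow(x$ground_truth$probes), "ground-truth probes\n")
  invisible(x)
}

benchmark_activity_table <- function(entries) {
  data.frame(molecule_id = vapply(entries, function(e) e$mol$id,
                                  character(1)),
             value = vapply(entries, `[[`, numeric(1), "pki"),
             units = "pKi", stringsAsFactors = FALSE)
}

#' Write a benchmark to disk in standard formats
#'
#' SDF for ligands and reference poses, PDB + SDF for pockets and their
#' cognate ligands, CSV activities, the pocketmol text format for the
#' ground truth, and a JSON manifest.
#'
#' @param bm a `pm_benchmark`.
#' @param dir output directory (created if needed).
#' @export
write_benchmark <- function(bm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_molecules(lapply(bm$train, `[[`, "mol"),
                  file.path(dir, "train.sdf"))
  write_molecules(lapply(bm$congeneric_test, `[[`, "mol"),
                  file.path(dir, "test_congeneric.sdf"))
  write_molecules(lapply(bm$diverse_test, `[[`, "mol"),
                  file.path(dir, "test_diverse.sdf"))
  write_molecules(lapply(bm$diverse_test, `[[`, "ref_pose"),
                  file.path(dir, "test_diverse_reference_poses.sdf"))
  utils::write.csv(benchmark_activity_table(c(bm$train, bm$congeneric_test,
                                              bm$diverse_test)),
                   file.path(dir, "activities.csv"), row.names = FALSE)
  for (k in seq_along(bm$pockets)) {
    pk <- bm$pockets[[k]]
    write_pocket_pdb(pk, file.path(dir, sprintf("%s.pdb", pk$id)))
    write_molecules(pk$cognate_ligand,
                    file.path(dir, sprintf("%s_ligand.sdf", pk$id)))
  }
  write_pocketmol(bm$ground_truth, file.path(dir, "ground_truth.pocketmol"))
  manifest <- list(seed = bm$seed, config = bm$config,
                   pockets = vapply(bm$pockets, `[[`, character(1), "id"),
                   n_train = length(bm$train),
                   n_congeneric_test = length(bm$congeneric_test),
                   n_diverse = length(bm$diverse_test))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
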