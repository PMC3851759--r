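# Internal helpers reused by the fixtures below.
probe_rows <- pocketmolr:::probe_rows
rot_xyz <- pocketmolr:::rot_xyz
with_seed <- pocketmolr:::with_seed

# Shared builders and pure-R reference oracles. The oracles deliberately
# re-derive every quantity with plain loops, independently of the
# package's computational path.

mk_mol <- function(id, el, coords, bonds = NULL) {
  molecule(id, el, matrix(coords, ncol = 3, byrow = TRUE), bonds)
}

# A rigid asymmetric 6-heavy-atom bead molecule with mixed typing.
hexa_mol <- function(id = "hexa") {
  mk_mol(id, c("C", "C", "C", "N", "O", "C", "H"),
         c(0, 0, 0,
           1.5, 0, 0,
           2.25, 1.3, 0,
           3.75, 1.3, 0,
           4.5, 2.6, 0,
           2.25, -1.3, 0.4,
           4.1, 0.45, -0.4),
         rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1),
               c(2, 6, 1), c(4, 7, 1)))
}

# Flexible chain with two rotatable bonds (slightly puckered so the
# geometry is genuinely 3D).
chain_mol <- function(id = "chain") {
  mk_mol(id, c("C", "C", "C", "C", "O"),
         c(0, 0, 0,
           1.5, 0, 0.1,
           2.25, 1.3, -0.2,
           3.75, 1.3, 0.25,
           4.5, 2.6, 0),
         rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(4, 5, 1)))
}

mk_probes <- function(type, xyz, dir = NULL, radius = NULL) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  if (is.null(radius))
    radius <- ifelse(type == "steric", 1.7, 1.4)
  if (!is.null(dir)) dir <- matrix(dir, ncol = 3, byrow = TRUE)
  probe_rows(type, xyz, dir, radius)
}

mk_pocket <- function(id, cls, xyz, cognate = NULL) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  el <- c(hydrophobic = "C", donor = "N", acceptor = "O",
          donor_acceptor = "O", neutral = "C")[cls]
  atoms <- data.frame(element = unname(el), interaction_class = cls,
                      vdw_radius = vdw_radius(el), is_hydrogen = FALSE,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  if (is.null(cognate)) cognate <- pose(hexa_mol(paste0(id, "_lig")),
                                        provenance = "crystal")
  protein_pocket(id, atoms, cognate)
}

random_rigid <- function() {
  list(R = rot_xyz(stats::runif(3, 0, 2 * pi)), t = stats::runif(3, -5, 5))
}

apply_rigid_pose <- function(p, tf) {
  pose(p$mol, sweep(p$coords %*% t(tf$R), 2, tf$t, "+"), p$provenance)
}

## ---- reference oracles ----------------------------------------------------

# Plain-R atom-probe scoring (independent of the C++ kernel).
r_ramp <- function(d, a, b, c) {
  if (d <= a || d >= c) return(0)
  if (d <= b) return((d - a) / (b - a))
  (c - d) / (c - b)
}

r_score_pose <- function(p, probes, params = score_params()) {
  hv <- which(!p$mol$atoms$is_hydrogen)
  cls <- p$mol$atoms$interaction_class[hv]
  rad <- p$mol$atoms$vdw_radius[hv]
  xyz <- p$coords[hv, , drop = FALSE]
  tot <- 0
  for (j in seq_len(nrow(probes))) {
    pp <- c(probes$x[j], probes$y[j], probes$z[j])
    for (i in seq_len(nrow(xyz))) {
      d <- sqrt(sum((xyz[i, ] - pp)^2))
      d0 <- rad[i] + probes$radius[j]
      depth <- (d0 - 0.5) - d
      if (depth > 0) tot <- tot - params$wc * depth^2
      if (probes$type[j] == "steric") {
        if (cls[i] == "hydrophobic")
          tot <- tot + params$wh * r_ramp(d, d0 - 0.3, d0, d0 + 1.5)
      } else {
        match <- (probes$type[j] == "donor" &&
                    cls[i] %in% c("acceptor", "donor_acceptor")) ||
                 (probes$type[j] == "acceptor" &&
                    cls[i] %in% c("donor", "donor_acceptor"))
        if (match && d > 1e-9) {
          r <- r_ramp(d, params$polar_lo, params$polar_ideal,
                      params$polar_hi)
          ca <- sum((xyz[i, ] - pp) *
                      c(probes$dx[j], probes$dy[j], probes$dz[j])) / d
          if (r > 0 && ca > 0) tot <- tot + params$wp * r * ca^2
        }
      }
    }
  }
  tot
}

# Plain-R Gaussian-overlap similarity for two poses.
r_overlap <- function(A, sa, B, sb) {
  tot <- 0
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B))) {
      s2 <- sa[i]^2 + sb[j]^2
      d2 <- sum((A[i, ] - B[j, ])^2)
      tot <- tot + (2 * pi * sa[i]^2 * sb[j]^2 / s2)^1.5 * exp(-d2 / (2 * s2))
    }
  tot
}

# Brute-force tie-corrected Kendall tau (tau-b).
r_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx * dy > 0) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# A small scored pocketmol + training set built from a known probe layout.
tiny_model_fixture <- function(seed = 1) {
  gt <- pocketmol(rbind(
    mk_probes("steric", c(0, 0, 3.4)),
    mk_probes("steric", c(1.5, 0, -3.4)),
    mk_probes("acceptor", c(3.75, 1.3, 2.9), dir = c(0, 0, -1)),
    mk_probes("donor", c(4.5, 2.6, -2.9), dir = c(0, 0, 1))),
    provenance = "ground_truth")
  gt
}

# A compact self-consistent training problem: activities generated from a
# known probe layout scored against each record's own pose ensemble, so
# the generating model is a perfect solution within the candidate pool.
make_tiny_training <- function(n = 6, seed = 5, noise = 0,
                               gt = tiny_model_fixture()) {
  mols <- lapply(seq_len(n), function(k) {
    m <- hexa_mol(sprintf("t%02d", k))
    # small per-molecule geometric variation
    m$conformers[[1]] <- m$conformers[[1]] +
      with_seed(seed + k, matrix(stats::rnorm(nrow(m$atoms) * 3, 0, 0.15),
                                 ncol = 3))
    m
  })
  training <- lapply(seq_along(mols), function(k) {
    ens <- with_seed(seed + 10 + k, lapply(1:6, function(j)
      pose(mols[[k]], mols[[k]]$conformers[[1]] +
             matrix(c(stats::rnorm(3, 0, 0.3)), nrow(mols[[k]]$atoms), 3,
                    byrow = TRUE))))
    sc <- ligand_score(ens, gt)$score
    pki <- sc + if (noise > 0) with_seed(seed + 20 + k,
                                         stats::rnorm(1, 0, noise)) else 0
    training_record(mols[[k]], pki, ens)
  })
  list(gt = gt, training = training)
}


# Session-level cache for the small benchmark reused across test files.
.fixture_cache <- new.env(parent = emptyenv())
cache_benchmark <- function(bm) assign("bm", bm, envir = .fixture_cache)
cached_benchmark <- function() {
  if (!exists("bm", envir = .fixture_cache))
    cache_benchmark(make_benchmark(11, benchmark_config(
      n_variants = 2, n_train = 6, n_congeneric_test = 3, n_diverse = 3,
      gt_size = 25, noise_sd = 0)))
  get("bm", envir = .fixture_cache)
}
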