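# Core containers: molecules, poses, protein pockets, probes, pocketmols.
# Plain S3 lists; coordinates are numeric matrices in Angstroms, all in the
# single pre-aligned model frame.

INTERACTION_CLASSES <- c("hydrophobic", "donor", "acceptor", "donor_acceptor",
                         "neutral")
PROBE_TYPES <- c("steric", "donor", "acceptor")

# Bondi-style van der Waals radii (Angstrom).
VDW_TABLE <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.10,
               F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom; unknown elements get the
#'   carbon radius with a warning.
#' @export
vdw_radius <- function(element) {
  r <- unname(VDW_TABLE[element])
  if (anyNA(r)) {
    warning("unknown element(s): ",
            paste(unique(element[is.na(r)]), collapse = ", "),
            "; using carbon radius")
    r[is.na(r)] <- VDW_TABLE[["C"]]
  }
  r
}

class_code <- function(cls) match(cls, INTERACTION_CLASSES)
ptype_code <- function(pt) match(pt, PROBE_TYPES)

#' Construct a molecule
#'
#' @param id molecule identifier.
#' @param elements character vector of element symbols.
#' @param coords numeric |atoms| x 3 matrix (conformer 0).
#' @param bonds integer matrix with columns (i, j, order); may have 0 rows.
#' @param interaction_class optional character vector; when NULL, classes are
#'   assigned from the element/bond rule table.
#' @return an object of class `pm_mol` with fields `id`, `atoms` (data frame
#'   with element, interaction_class, vdw_radius, is_hydrogen),
#'   `bonds`, `rotatable_bonds`, and `conformers` (list of coordinate sets).
#' @export
molecule <- function(id, elements, coords, bonds = NULL,
                     interaction_class = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(nrow(coords) == length(elements), ncol(coords) == 3)
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 3)
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (nrow(bonds) && (max(bonds[, 1:2]) > length(elements) ||
                      min(bonds[, 1:2]) < 1))
    stop("bond indices out of range for molecule '", id, "'")
  atoms <- data.frame(element = as.character(elements),
                      interaction_class = NA_character_,
                      vdw_radius = vdw_radius(elements),
                      is_hydrogen = elements == "H",
                      stringsAsFactors = FALSE)
  mol <- structure(list(id = id, atoms = atoms, bonds = bonds,
                        rotatable_bonds = integer(0),
                        conformers = list(coords)),
                   class = "pm_mol")
  if (is.null(interaction_class)) {
    mol <- assign_interaction_classes(mol)
  } else {
    stopifnot(all(interaction_class %in% INTERACTION_CLASSES))
    mol$atoms$interaction_class <- interaction_class
  }
  mol$rotatable_bonds <- find_rotatable_bonds(mol)
  mol
}

#' @export
print.pm_mol <- function(x, ...) {
  cat("<pm_mol>", x$id, ":", nrow(x$atoms), "atoms (",
      sum(!x$atoms$is_hydrogen), "heavy ),", nrow(x$bonds), "bonds,",
      length(x$conformers), "conformer(s)\n")
  invisible(x)
}

heavy_idx <- function(mol) which(!mol$atoms$is_hydrogen)

#' Construct a pose
#'
#' A pose is one placed conformation of a molecule in the common model frame.
#'
#' @param mol a `pm_mol`.
#' @param coords |atoms| x 3 coordinate matrix (same atom ordering as `mol`).
#' @param provenance one of input, conformer, docked, similarity_aligned,
#'   refined, crystal.
#' @param score optional cached score.
#' @param source_pocket optional id of the pocket the pose was docked into.
#' @export
pose <- function(mol, coords = mol$conformers[[1]], provenance = "input",
                 score = NA_real_, source_pocket = NA_character_) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(mol$atoms), all(is.finite(coords)))
  provenance <- match.arg(provenance,
                          c("input", "conformer", "docked",
                            "similarity_aligned", "refined", "crystal"))
  structure(list(molecule_id = mol$id, mol = mol, coords = coords,
                 provenance = provenance, score = score,
                 source_pocket = source_pocket),
            class = "pm_pose")
}

#' @export
print.pm_pose <- function(x, ...) {
  cat("<pm_pose>", x$molecule_id, "(", x$provenance, ")",
      if (!is.na(x$score)) sprintf("score %.3f", x$score), "\n")
  invisible(x)
}

pose_heavy_coords <- function(p) p$coords[heavy_idx(p$mol), , drop = FALSE]

#' Construct a protein pocket
#'
#' @param id pocket identifier.
#' @param atoms data frame with columns element, interaction_class,
#'   vdw_radius, is_hydrogen, x, y, z (binding-site subset, pre-aligned).
#' @param cognate a `pm_pose` for the co-crystallized ligand
#'   (provenance crystal).
#' @param source source structure identifier (e.g. a PDB code).
#' @export
protein_pocket <- function(id, atoms, cognate, source = id) {
  stopifnot(all(c("element", "interaction_class", "x", "y", "z") %in%
                  names(atoms)),
            inherits(cognate, "pm_pose"))
  if (is.null(atoms$vdw_radius)) atoms$vdw_radius <- vdw_radius(atoms$element)
  if (is.null(atoms$is_hydrogen)) atoms$is_hydrogen <- atoms$element == "H"
  structure(list(id = id, atoms = atoms, cognate_ligand = cognate,
                 source = source),
            class = "pm_pocket")
}

#' @export
print.pm_pocket <- function(x, ...) {
  cat("<pm_pocket>", x$id, ":", nrow(x$atoms), "atoms; cognate",
      x$cognate_ligand$molecule_id, "\n")
  invisible(x)
}

pocket_coords <- function(pk) as.matrix(pk$atoms[, c("x", "y", "z")])

#' Construct a probe set (pocketmol)
#'
#' @param probes data frame with columns type (steric/donor/acceptor),
#'   x, y, z, dx, dy, dz (unit direction; NA for steric), radius.
#' @param provenance one of ligand_only, structure_guided, ground_truth.
#' @param density_label free-text label for the probe-density setting.
#' @export
pocketmol <- function(probes, provenance = "ligand_only",
                      density_label = "") {
  provenance <- match.arg(provenance,
                          c("ligand_only", "structure_guided", "ground_truth"))
  stopifnot(all(c("type", "x", "y", "z", "dx", "dy", "dz", "radius") %in%
                  names(probes)),
            all(probes$type %in% PROBE_TYPES), all(probes$radius > 0))
  polar <- probes$type != "steric"
  if (any(polar)) {
    nrm <- sqrt(probes$dx[polar]^2 + probes$dy[polar]^2 + probes$dz[polar]^2)
    if (any(abs(nrm - 1) > 1e-6))
      stop("polar probe directions must be unit vectors")
  }
  rownames(probes) <- NULL
  structure(list(probes = probes, provenance = provenance,
                 density_label = density_label),
            class = "pm_pocketmol")
}

#' @export
print.pm_pocketmol <- function(x, ...) {
  cat("<pm_pocketmol>", nrow(x$probes), "probes (",
      paste(names(table(x$probes$type)), table(x$probes$type),
            collapse = ", "),
      ") provenance:", x$provenance, x$density_label, "\n")
  invisible(x)
}

probe_rows <- function(type, xyz, dir = NULL, radius) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(dir)) dir <- matrix(NA_real_, n, 3)
  data.frame(type = rep(type, length.out = n), x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], dx = dir[, 1], dy = dir[, 2], dz = dir[, 3],
             radius = rep(radius, length.out = n), stringsAsFactors = FALSE)
}

## ---- geometry helpers -----------------------------------------------------

# Rotation matrix from xyz Euler angles (radians).
rot_xyz <- function(a) {
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Rotate coords about `center` by Euler angles, then translate.
transform_coords <- function(coords, angles, shift, center) {
  R <- rot_xyz(angles)
  sweep(sweep(coords, 2, center) %*% t(R), 2, center + shift, "+")
}

# Principal axes (right-handed) of a point set.
principal_axes <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  cv <- crossprod(cc) / max(1, nrow(cc) - 1)
  e <- eigen(cv, symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

# Plain RMSD between two coordinate matrices (no superposition).
rmsd_direct <- function(X, Y) {
  stopifnot(nrow(X) == nrow(Y))
  sqrt(mean(rowSums((X - Y)^2)))
}

# Minimum RMSD after optimal rigid superposition (Kabsch).
rmsd_superposed <- function(X, Y) {
  xc <- sweep(X, 2, colMeans(X))
  yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(yc, xc))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd_direct(xc, yc %*% R)
}
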