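# Molecule / pocket I/O, interaction typing, conformer generation,
# activity unit handling.

## ---- interaction classes --------------------------------------------------

#' Assign interaction classes to molecule atoms
#'
#' Rule table (pharmacophore-style typing):
#' \itemize{
#'   \item donor: N or S with at least one bonded hydrogen;
#'   \item donor_acceptor: O with at least one bonded hydrogen
#'     (hydroxyl, water);
#'   \item acceptor: N or O with no bonded hydrogen (carbonyl O, ether O,
#'     nitrile N, pyridine N);
#'   \item hydrophobic: C or S bonded only to C/H/S, and halogens;
#'   \item neutral: everything else (including all hydrogens).
#' }
#' Re-assignment is idempotent; unknown elements become neutral with a
#' warning.
#'
#' @param mol a `pm_mol`.
#' @return the molecule with `atoms$interaction_class` filled in.
#' @export
assign_interaction_classes <- function(mol) {
  el <- mol$atoms$element
  n <- length(el)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  has_h <- vapply(seq_len(n), function(i) any(el[nb[[i]]] == "H"), logical(1))
  only_chs <- vapply(seq_len(n), function(i)
    all(el[nb[[i]]] %in% c("C", "H", "S")), logical(1))
  cls <- rep("neutral", n)
  known <- el %in% names(VDW_TABLE)
  if (any(!known))
    warning("unknown element(s) assigned neutral class: ",
            paste(unique(el[!known]), collapse = ", "))
  cls[el %in% c("F", "Cl", "Br", "I")] <- "hydrophobic"
  cls[el == "C" & only_chs] <- "hydrophobic"
  cls[el == "S" & only_chs & !has_h] <- "hydrophobic"
  cls[el == "N" & has_h] <- "donor"
  cls[el == "S" & has_h] <- "donor"
  cls[el == "N" & !has_h] <- "acceptor"
  cls[el == "O" & !has_h] <- "acceptor"
  cls[el == "O" & has_h] <- "donor_acceptor"
  cls[el == "H"] <- "neutral"
  mol$atoms$interaction_class <- cls
  mol
}

## ---- rotatable bonds & conformers ----------------------------------------

# Undirected adjacency list from the bond table.
bond_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  if (nrow(mol$bonds)) {
    for (r in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

# Atoms reachable from `start` without traversing bond row `skip`.
reachable_without <- function(mol, start, skip) {
  nb <- bond_adjacency(mol)
  bi <- mol$bonds[skip, 1]; bj <- mol$bonds[skip, 2]
  seen <- rep(FALSE, nrow(mol$atoms))
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in nb[[v]]) {
      if ((v == bi && w == bj) || (v == bj && w == bi)) next
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  which(seen)
}

find_rotatable_bonds <- function(mol) {
  if (!nrow(mol$bonds)) return(integer(0))
  el <- mol$atoms$element
  nb <- bond_adjacency(mol)
  heavy_deg <- vapply(nb, function(x) sum(el[x] != "H"), integer(1))
  out <- integer(0)
  for (r in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
    if (mol$bonds[r, 3] != 1L) next
    if (el[i] == "H" || el[j] == "H") next
    if (heavy_deg[i] < 2 || heavy_deg[j] < 2) next
    side <- reachable_without(mol, j, r)
    if (i %in% side) next  # bond is in a ring
    out <- c(out, r)
  }
  out
}

# Rodrigues rotation of points about axis through `origin`.
rotate_about_axis <- function(coords, origin, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  v <- sweep(coords, 2, origin)
  kv <- v %*% k
  cross <- cbind(k[2] * v[, 3] - k[3] * v[, 2],
                 k[3] * v[, 1] - k[1] * v[, 3],
                 k[1] * v[, 2] - k[2] * v[, 1])
  rot <- v * cos(theta) + cross * sin(theta) +
    outer(as.vector(kv), k) * (1 - cos(theta))
  sweep(rot, 2, origin, "+")
}

# Nonbonded heavy-atom pairs (graph distance >= 3).
nonbonded_pairs <- function(mol) {
  n <- nrow(mol$atoms)
  if (n < 2) return(matrix(integer(0), 0, 2))
  nb <- bond_adjacency(mol)
  excl <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    excl[i, i] <- TRUE
    for (j in nb[[i]]) {
      excl[i, j] <- TRUE
      for (k in nb[[j]]) excl[i, k] <- TRUE  # 1-3
    }
  }
  hv <- heavy_idx(mol)
  prs <- which(upper.tri(excl) & !excl, arr.ind = TRUE)
  prs[prs[, 1] %in% hv & prs[, 2] %in% hv, , drop = FALSE]
}

has_internal_clash <- function(mol, coords, frac = 0.7) {
  prs <- nonbonded_pairs(mol)
  if (!nrow(prs)) return(FALSE)
  r <- mol$atoms$vdw_radius
  d <- sqrt(rowSums((coords[prs[, 1], , drop = FALSE] -
                       coords[prs[, 2], , drop = FALSE])^2))
  any(d < frac * (r[prs[, 1]] + r[prs[, 2]]))
}

#' Generate a bounded, diverse conformer ensemble
#'
#' Torsion driving over rotatable bonds at staggered offsets
#' (0, +60, -60, 180 degrees), screened by an intramolecular clash filter
#' (no nonbonded heavy-atom pair closer than 70\% of the radii sum) and
#' selected greedily for diversity (pairwise heavy-atom RMSD after optimal
#' superposition at least `diversity_min`). Deterministic given `seed`.
#' Rigid molecules keep their single input conformer.
#'
#' @param mol a `pm_mol` with at least one conformer.
#' @param max_n maximum number of conformers (default 5).
#' @param seed integer seed.
#' @param diversity_min minimum pairwise superposed heavy-atom RMSD (Angstrom).
#' @return the molecule with `conformers` replaced.
#' @export
generate_conformers <- function(mol, max_n = 5, seed = 1,
                                diversity_min = 0.5) {
  rot <- mol$rotatable_bonds
  base <- mol$conformers[[1]]
  if (!length(rot) || max_n <= 1) {
    mol$conformers <- list(base)
    return(mol)
  }
  angles <- c(0, 60, -60, 180) * pi / 180
  nrot <- length(rot)
  combos <- if (4^nrot <= 81) {
    as.matrix(expand.grid(rep(list(seq_along(angles)), nrot)))
  } else {
    with_seed(seed, {
      m <- matrix(sample.int(length(angles), 81 * nrot, replace = TRUE),
                  ncol = nrot)
      unique(rbind(rep(1L, nrot), m))
    })
  }
  hv <- heavy_idx(mol)
  cands <- list()
  for (ci in seq_len(nrow(combos))) {
    cc <- base
    ok <- TRUE
    for (b in seq_len(nrot)) {
      th <- angles[combos[ci, b]]
      if (abs(th) < 1e-12) next
      r <- rot[b]
      i <- mol$bonds[r, 1]; j <- mol$bonds[r, 2]
      side <- reachable_without(mol, j, r)
      side <- setdiff(side, j)
      if (!length(side)) next
      cc[side, ] <- rotate_about_axis(cc[side, , drop = FALSE],
                                      cc[j, ], cc[j, ] - cc[i, ], th)
    }
    if (has_internal_clash(mol, cc)) ok <- FALSE
    if (ok) cands[[length(cands) + 1L]] <- cc
  }
  if (!length(cands)) cands <- list(base)
  # greedy max-min diversity selection, original conformer first
  keep <- list(base)
  while (length(keep) < max_n && length(cands)) {
    dmin <- vapply(cands, function(cc)
      min(vapply(keep, function(kk)
        rmsd_superposed(cc[hv, , drop = FALSE], kk[hv, , drop = FALSE]),
        numeric(1))), numeric(1))
    best <- which.max(dmin)
    if (dmin[best] < diversity_min) break
    keep[[length(keep) + 1L]] <- cands[[best]]
    cands <- cands[-best]
  }
  mol$conformers <- keep
  mol
}

## ---- activities -----------------------------------------------------------

#' Convert an activity value to pKi
#'
#' pKi = -log10(value in molar); pKi values pass through unchanged
#' (9.0 is equivalent to a Ki of 1 nM).
#'
#' @param value numeric activity value(s), positive for concentration units.
#' @param units one of M, mM, uM, nM, pKi.
#' @export
activity_to_pki <- function(value, units = c("M", "mM", "uM", "nM", "pKi")) {
  units <- match.arg(units)
  if (units == "pKi") return(as.numeric(value))
  if (any(value <= 0)) stop("concentration values must be positive")
  fac <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[units]]
  -log10(value * fac)
}

#' Read an activity table
#'
#' CSV with columns molecule_id, value, units; returns a data frame with a
#' computed `pki` column.
#' @param path file path.
#' @export
read_activities <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("molecule_id", "value", "units") %in% names(df)))
  df$pki <- vapply(seq_len(nrow(df)), function(i)
    activity_to_pki(df$value[i], df$units[i]), numeric(1))
  df
}

## ---- SDF ------------------------------------------------------------------

#' Read molecules from SDF or MOL2
#'
#' Input 3D coordinates become conformer 0; interaction classes are assigned
#' on read. Records without 3D coordinates (all-zero z) are an error.
#'
#' @param path file path.
#' @param format "sdf" (V2000, via ChemmineR) or "mol2" (via bio3d).
#' @return list of `pm_mol`.
#' @export
read_molecules <- function(path, format = c("sdf", "mol2")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "sdf") read_sdf_molecules(path) else read_mol2_molecules(path)
}

read_sdf_molecules <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(lines)))) return(list())
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e) stop("cannot parse SDF: ",
                                            conditionMessage(e)))
  valid <- suppressWarnings(ChemmineR::validSDF(sdfs))
  rec_text <- split(lines, cumsum(c(0, head(lines == "$$$$", -1))))
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    rec <- tryCatch({
      if (valid[k]) {
        sdf <- sdfs[[k]]
        ab <- ChemmineR::atomblock(sdf)
        bb <- ChemmineR::bondblock(sdf)
        el <- gsub("_.*$", "", rownames(ab))
        coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
        bonds <- if (length(bb)) {
          matrix(as.integer(as.matrix(bb[, 1:3, drop = FALSE])), ncol = 3)
        } else NULL
        id <- unname(as.character(ChemmineR::sdfid(sdf)))
        if (!length(id) || is.na(id) || !nzchar(id))
          id <- sprintf("mol_%03d", k)
        mol <- list(id = id, el = el, coords = coords, bonds = bonds)
      } else {
        # bond-less records are valid V2000 but rejected by ChemmineR;
        # parse the fixed-width block directly
        mol <- parse_sdf_v2000(rec_text[[k]], k)
      }
      if (nrow(mol$coords) > 1 && all(abs(mol$coords[, 3]) < 1e-8))
        stop("no 3D coordinates")
      molecule(mol$id, mol$el, mol$coords, mol$bonds)
    }, error = function(e)
      stop("SDF record ", k, ": ", conditionMessage(e), call. = FALSE))
    out[[k]] <- rec
  }
  out
}

# Minimal V2000 fallback for records ChemmineR will not hold (e.g. a
# molecule with no bonds).
parse_sdf_v2000 <- function(rl, k) {
  rl <- rl[rl != "$$$$"]
  if (length(rl) < 4) stop("truncated record")
  na <- as.integer(substr(rl[4], 1, 3))
  nb <- as.integer(substr(rl[4], 4, 6))
  if (is.na(na) || na < 1) stop("bad counts line")
  at <- rl[4 + seq_len(na)]
  coords <- cbind(as.numeric(substr(at, 1, 10)),
                  as.numeric(substr(at, 11, 20)),
                  as.numeric(substr(at, 21, 30)))
  el <- trimws(substr(at, 31, 34))
  bonds <- NULL
  if (!is.na(nb) && nb > 0) {
    bl <- rl[4 + na + seq_len(nb)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)),
                   as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
  }
  id <- trimws(rl[1])
  if (!nzchar(id)) id <- sprintf("mol_%03d", k)
  list(id = id, el = el, coords = coords, bonds = bonds)
}

read_mol2_molecules <- function(path) {
  m2 <- tryCatch(bio3d::read.mol2(path),
                 error = function(e) stop("cannot parse MOL2: ",
                                          conditionMessage(e)))
  recs <- if (inherits(m2, "mol2")) list(m2) else m2
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    out[[k]] <- tryCatch({
      r <- recs[[k]]
      at <- r$atom
      el <- sub("\\..*$", "", at$elena)
      el2 <- sub("\\..*$", "", at$elety)
      el[!el %in% names(VDW_TABLE) & el2 %in% names(VDW_TABLE)] <-
        el2[!el %in% names(VDW_TABLE) & el2 %in% names(VDW_TABLE)]
      coords <- as.matrix(at[, c("x", "y", "z")])
      if (nrow(coords) > 1 && all(abs(coords[, 3]) < 1e-8))
        stop("no 3D coordinates")
      bonds <- if (!is.null(r$bond) && nrow(r$bond)) {
        ord <- suppressWarnings(as.integer(r$bond$type))
        ord[is.na(ord)] <- 1L  # aromatic and amide orders
        cbind(as.integer(r$bond$origin), as.integer(r$bond$target), ord)
      } else NULL
      id <- if (!is.null(r$name) && nzchar(r$name)) r$name
            else sprintf("mol_%03d", k)
      molecule(id, el, coords, bonds)
    }, error = function(e)
      stop("MOL2 record ", k, ": ", conditionMessage(e), call. = FALSE))
  }
  out
}

#' Write molecules or poses to SDF (V2000) or MOL2
#'
#' @param mols list of `pm_mol` (conformer 0 written) and/or `pm_pose`.
#' @param path output path.
#' @param format "sdf" or "mol2".
#' @param tags optional named list of per-record data fields (SDF only);
#'   each element a vector of length |mols|.
#' @export
write_molecules <- function(mols, path, format = c("sdf", "mol2"),
                            tags = NULL) {
  format <- match.arg(format)
  if (inherits(mols, c("pm_mol", "pm_pose"))) mols <- list(mols)
  lines <- character(0)
  for (k in seq_along(mols)) {
    x <- mols[[k]]
    if (inherits(x, "pm_pose")) {
      mol <- x$mol; coords <- x$coords
    } else {
      mol <- x; coords <- mol$conformers[[1]]
    }
    tg <- if (is.null(tags)) NULL else lapply(tags, `[`, k)
    lines <- c(lines, if (format == "sdf") sdf_record(mol, coords, tg)
                      else mol2_record(mol, coords))
  }
  writeLines(lines, path)
  invisible(path)
}

sdf_record <- function(mol, coords, tags = NULL) {
  n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  out <- c(mol$id, "  pocketmolr", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  out <- c(out, vapply(seq_len(n), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[i, 1], coords[i, 2], coords[i, 3],
            mol$atoms$element[i]), character(1)))
  if (nb)
    out <- c(out, vapply(seq_len(nb), function(r)
      sprintf("%3d%3d%3d  0", mol$bonds[r, 1], mol$bonds[r, 2],
              mol$bonds[r, 3]), character(1)))
  out <- c(out, "M  END")
  for (nm in names(tags))
    out <- c(out, sprintf("> <%s>", nm), as.character(tags[[nm]]), "")
  c(out, "$$$$")
}

mol2_record <- function(mol, coords) {
  n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
  out <- c("@<TRIPOS>MOLECULE", mol$id,
           sprintf("%5d %5d     1", n, nb),
           "SMALL", "NO_CHARGES", "", "@<TRIPOS>ATOM")
  out <- c(out, vapply(seq_len(n), function(i)
    sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s 1 LIG 0.0000",
            i, paste0(mol$atoms$element[i], i), coords[i, 1], coords[i, 2],
            coords[i, 3], mol$atoms$element[i]), character(1)))
  out <- c(out, "@<TRIPOS>BOND")
  if (nb)
    out <- c(out, vapply(seq_len(nb), function(r)
      sprintf("%6d %5d %5d %s", r, mol$bonds[r, 1], mol$bonds[r, 2],
              mol$bonds[r, 3]), character(1)))
  out
}

## ---- protein pockets ------------------------------------------------------

# Element + atom-name heuristic for protein atoms (no bond records in PDB):
# C/S hydrophobic; N donor; O acceptor, except hydroxyl-type names
# (OG, OG1, OH, OW) and water O which are donor_acceptor; H neutral.
pdb_interaction_class <- function(element, elety, resid = "") {
  cls <- rep("neutral", length(element))
  cls[element %in% c("C", "S")] <- "hydrophobic"
  cls[element == "N"] <- "donor"
  cls[element == "O"] <- "acceptor"
  da <- element == "O" & (toupper(elety) %in% c("OG", "OG1", "OH", "OW") |
                            resid %in% c("HOH", "WAT"))
  cls[da] <- "donor_acceptor"
  cls
}

#' Read a protein binding pocket from a PDB file
#'
#' Pocket atoms are protein heavy atoms (plus polar hydrogens when present,
#' i.e. hydrogens within 1.25 Angstrom of an N/O) within `pocket_cutoff` of
#' any heavy atom of the cognate ligand. The cognate ligand is either a
#' HETATM residue named by `ligand_selector` or a molecule read from an
#' SDF/MOL2 path. Frames are assumed pre-aligned; no re-alignment is done.
#'
#' @param pdb_path PDB file path.
#' @param ligand_selector residue name (e.g. "LIG") or path to an SDF/MOL2
#'   file holding the bound ligand in the same frame.
#' @param pocket_cutoff shell radius in Angstrom (default 5).
#' @param id pocket identifier (default: file base name).
#' @return a `pm_pocket`.
#' @export
read_pocket <- function(pdb_path, ligand_selector, pocket_cutoff = 5,
                        id = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(pdb_path, verbose = FALSE),
                  error = function(e) stop("cannot parse PDB: ",
                                           conditionMessage(e)))
  at <- pdb$atom
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(pdb_path))
  lig_is_file <- grepl("\\.(sdf|mol2)$", ligand_selector, ignore.case = TRUE)
  if (lig_is_file) {
    fmt <- if (grepl("\\.mol2$", ligand_selector, ignore.case = TRUE))
      "mol2" else "sdf"
    lig_mol <- read_molecules(ligand_selector, fmt)[[1]]
  } else {
    sel <- at$type == "HETATM" & at$resid == ligand_selector
    if (!any(sel)) stop("ligand '", ligand_selector, "' not found in ",
                        pdb_path)
    lat <- at[sel, ]
    el <- element_from_pdb(lat)
    lig_mol <- molecule(paste0(id, "_ligand"), el,
                        as.matrix(lat[, c("x", "y", "z")]))
  }
  cognate <- pose(lig_mol, provenance = "crystal")
  lig_heavy <- pose_heavy_coords(cognate)

  prot <- at[at$type == "ATOM", ]
  if (!nrow(prot)) stop("no protein atoms in ", pdb_path)
  el <- element_from_pdb(prot)
  xyz <- as.matrix(prot[, c("x", "y", "z")])
  is_h <- el == "H"
  # polar hydrogens: within covalent range of an N/O
  keep_h <- rep(FALSE, nrow(prot))
  if (any(is_h)) {
    no <- which(el %in% c("N", "O"))
    if (length(no)) {
      for (i in which(is_h)) {
        d <- sqrt(colSums((t(xyz[no, , drop = FALSE]) - xyz[i, ])^2))
        if (min(d) < 1.25) keep_h[i] <- TRUE
      }
    }
  }
  keep <- !is_h | keep_h
  prot <- prot[keep, ]; el <- el[keep]; xyz <- xyz[keep, , drop = FALSE]
  dmin <- apply(xyz, 1, function(p)
    min(sqrt(colSums((t(lig_heavy) - p)^2))))
  inshell <- dmin <= pocket_cutoff
  if (!any(inshell)) stop("empty pocket at cutoff ", pocket_cutoff, " A")
  prot <- prot[inshell, ]; el <- el[inshell]
  xyz <- xyz[inshell, , drop = FALSE]
  atoms <- data.frame(element = el,
                      interaction_class =
                        pdb_interaction_class(el, prot$elety, prot$resid),
                      vdw_radius = vdw_radius(el),
                      is_hydrogen = el == "H",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  protein_pocket(id, atoms, cognate, source = id)
}

element_from_pdb <- function(at) {
  el <- trimws(at$elesy)
  bad <- is.na(el) | !el %in% names(VDW_TABLE)
  if (any(bad)) {
    guess <- toupper(substr(trimws(at$elety[bad]), 1, 1))
    guess[guess == "L"] <- "Cl"
    el[bad] <- guess
  }
  el[!el %in% names(VDW_TABLE)] <- "C"
  el
}

# Minimal PDB writer for synthetic pockets. Atom names are chosen so that
# pdb_interaction_class() round-trips the typing:
# hydrophobic -> CB, donor -> N, acceptor -> O, donor_acceptor -> OG.
write_pocket_pdb <- function(pk, path) {
  nm <- c(hydrophobic = "CB", donor = "N", acceptor = "O",
          donor_acceptor = "OG", neutral = "CA")
  a <- pk$atoms
  lines <- vapply(seq_len(nrow(a)), function(i)
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, nm[[a$interaction_class[i]]], "PKT", i,
            a$x[i], a$y[i], a$z[i], a$element[i]), character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

## ---- pocketmol text format ------------------------------------------------

#' Write a pocketmol to its text format
#'
#' One probe per line: type, x, y, z, dx, dy, dz, radius (direction is
#' 0 0 0 for steric probes). A comment header records provenance and the
#' density label.
#' @param pm a `pm_pocketmol`.
#' @param path output path.
#' @export
write_pocketmol <- function(pm, path) {
  p <- pm$probes
  d <- as.matrix(p[, c("dx", "dy", "dz")])
  d[is.na(d)] <- 0
  hdr <- sprintf("# pocketmol provenance=%s density=%s", pm$provenance,
                 pm$density_label)
  lines <- vapply(seq_len(nrow(p)), function(i)
    sprintf("%s %.4f %.4f %.4f %.4f %.4f %.4f %.3f", p$type[i],
            p$x[i], p$y[i], p$z[i], d[i, 1], d[i, 2], d[i, 3], p$radius[i]),
    character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a pocketmol from its text format
#' @param path file path written by [write_pocketmol()].
#' @export
read_pocketmol <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  prov <- "ligand_only"; dens <- ""
  if (length(hdr)) {
    m <- regmatches(hdr[1],
                    regexec("provenance=(\\S+) density=(\\S*)", hdr[1]))[[1]]
    if (length(m) == 3) { prov <- m[2]; dens <- m[3] }
  }
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pocketmol file: ", path)
  parts <- strsplit(trimws(lines), "\\s+")
  df <- do.call(rbind, lapply(parts, function(x)
    data.frame(type = x[1], x = as.numeric(x[2]), y = as.numeric(x[3]),
               z = as.numeric(x[4]), dx = as.numeric(x[5]),
               dy = as.numeric(x[6]), dz = as.numeric(x[7]),
               radius = as.numeric(x[8]), stringsAsFactors = FALSE)))
  steric <- df$type == "steric"
  df[steric, c("dx", "dy", "dz")] <- NA_real_
  if (any(!steric)) {
    # renormalize directions written at fixed precision
    nrm <- sqrt(df$dx[!steric]^2 + df$dy[!steric]^2 + df$dz[!steric]^2)
    df$dx[!steric] <- df$dx[!steric] / nrm
    df$dy[!steric] <- df$dy[!steric] / nrm
    df$dz[!steric] <- df$dz[!steric] / nrm
  }
  pocketmol(df, provenance = prov, density_label = dens)
}
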