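# Probe tessellation of aligned active-ligand poses and structure-based
# probe filtering.

#' Tessellation configuration
#'
#' @param polar_dist ideal heavy-atom distance for polar probe placement
#'   (Angstrom, default 2.9).
#' @param min_probe_score minimum optimized single-probe interaction (pKd)
#'   for retention (default 0.02).
#' @param dedupe_radius same-type deduplication radius (default 0.5).
#' @param fine_opt logical; locally optimize each candidate's position
#'   (default TRUE).
#' @param fine_tether tether on fine optimization displacement (default 0.75).
#' @param fine_maxit Nelder-Mead iteration cap for fine optimization.
#' @param clash_slack how deeply (Angstrom) a candidate may sit inside the
#'   contact distance of a non-parent source atom before being discarded.
#' @export
tessellation_config <- function(polar_dist = 2.9, min_probe_score = 0.02,
                                dedupe_radius = 0.5, fine_opt = TRUE,
                                fine_tether = 0.75, fine_maxit = 30,
                                clash_slack = 0.4) {
  list(polar_dist = polar_dist, min_probe_score = min_probe_score,
       dedupe_radius = dedupe_radius, fine_opt = fine_opt,
       fine_tether = fine_tether, fine_maxit = fine_maxit,
       clash_slack = clash_slack)
}

# 14 direction samples: 6 axial + 8 diagonal unit vectors.
probe_directions <- function() {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  unname(rbind(ax, dg))
}

#' Construct a probe pool
#'
#' @param probes probe data frame (see [pocketmol()] for the columns).
#' @param source_pose_ids per-probe provenance identifiers.
#' @param filtered has the pool been structure-filtered?
#' @param score optional per-probe tessellation scores.
#' @export
probe_pool <- function(probes, source_pose_ids, filtered = FALSE,
                       score = NULL) {
  rownames(probes) <- NULL
  structure(list(probes = probes, source_pose_ids = source_pose_ids,
                 filtered = filtered, score = score),
            class = "pm_probepool")
}

#' @export
print.pm_probepool <- function(x, ...) {
  cat("<pm_probepool>", nrow(x$probes), "probes",
      if (x$filtered) "(filtered)" else "(unfiltered)", "\n")
  invisible(x)
}

# Single-probe interaction of one candidate probe against one pose.
single_probe_score <- function(xyz, type, dir, radius, pose_args, params) {
  pr <- probe_rows(type, matrix(xyz, 1), if (is.null(dir)) NULL
                   else matrix(dir, 1), radius)
  pa <- probe_cpp_args(pr)
  res <- cpp_score_terms(pose_args$coords, pose_args$aclass, pose_args$avdw,
                         pa$P, pa$ptype, pa$pdir, pa$prad, params$wh,
                         params$wp, params$wc, params$polar_lo,
                         params$polar_ideal, params$polar_hi)
  res$hydrophobic_term + res$polar_term + res$penalty_term
}

#' Tessellate active-ligand poses into a candidate probe pool
#'
#' For every heavy atom of every pose: steric probes are placed at contact
#' distance along 14 outward directions from hydrophobic atoms; donor
#' probes opposite acceptor atoms and acceptor probes opposite donor atoms
#' at the polar ideal distance, with the probe direction pointing at the
#' ligand atom (donor_acceptor atoms spawn both). Candidates clashing with
#' the rest of the source pose are discarded; remaining candidates are
#' fine-optimized by tethered local maximization of their single-probe
#' interaction with the source pose, kept only if that interaction exceeds
#' `min_probe_score`, and deduplicated at `dedupe_radius` (same type,
#' better-scoring probe kept).
#'
#' @param active_poses nonempty list of `pm_pose` (active training
#'   ligands, aligned in the common frame).
#' @param config a [tessellation_config()].
#' @param params scoring parameters.
#' @return a `pm_probepool` (unfiltered).
#' @export
tessellate <- function(active_poses, config = tessellation_config(),
                       params = score_params()) {
  if (!length(active_poses)) stop("no active poses to tessellate")
  dirs <- probe_directions()
  cand <- list()
  for (pi in seq_along(active_poses)) {
    p <- active_poses[[pi]]
    hv <- heavy_idx(p$mol)
    cls <- p$mol$atoms$interaction_class[hv]
    rad <- p$mol$atoms$vdw_radius[hv]
    xyz <- p$coords[hv, , drop = FALSE]
    pose_args <- list(coords = xyz, aclass = class_code(cls), avdw = rad)
    pid <- if (!is.null(p$molecule_id)) paste0(p$molecule_id, "#", pi)
           else as.character(pi)
    for (ai in seq_len(nrow(xyz))) {
      specs <- list()
      if (cls[ai] == "hydrophobic")
        specs <- c(specs, list(list(type = "steric",
                                    dist = rad[ai] + params$steric_radius,
                                    prad = params$steric_radius)))
      if (cls[ai] %in% c("donor", "donor_acceptor"))
        specs <- c(specs, list(list(type = "acceptor",
                                    dist = config$polar_dist,
                                    prad = params$polar_radius)))
      if (cls[ai] %in% c("acceptor", "donor_acceptor"))
        specs <- c(specs, list(list(type = "donor",
                                    dist = config$polar_dist,
                                    prad = params$polar_radius)))
      if (!length(specs)) next
      for (sp in specs) {
        for (di in seq_len(nrow(dirs))) {
          pos <- xyz[ai, ] + dirs[di, ] * sp$dist
          # clash pre-screen against the other atoms of the source pose
          d <- sqrt(colSums((t(xyz) - pos)^2))
          lim <- rad + sp$prad - config$clash_slack
          lim[ai] <- 0
          if (any(d < lim)) next
          dirvec <- if (sp$type == "steric") NULL else {
            v <- xyz[ai, ] - pos
            v / sqrt(sum(v^2))
          }
          sc <- single_probe_score(pos, sp$type, dirvec, sp$prad, pose_args,
                                   params)
          if (config$fine_opt) {
            fobj <- function(q) {
              if (sqrt(sum((q - pos)^2)) > config$fine_tether) return(1e6)
              dv <- if (sp$type == "steric") NULL else {
                v <- xyz[ai, ] - q
                n <- sqrt(sum(v^2))
                if (n < 1e-9) return(1e6)
                v / n
              }
              -single_probe_score(q, sp$type, dv, sp$prad, pose_args, params)
            }
            opt <- stats::optim(pos, fobj, method = "Nelder-Mead",
                                control = list(maxit = config$fine_maxit,
                                               reltol = 1e-6))
            if (-opt$value > sc) {
              pos <- opt$par
              sc <- -opt$value
              if (sp$type != "steric") {
                v <- xyz[ai, ] - pos
                dirvec <- v / sqrt(sum(v^2))
              }
            }
          }
          if (sc < config$min_probe_score) next
          cand[[length(cand) + 1L]] <-
            list(row = probe_rows(sp$type, pos, if (is.null(dirvec)) NULL
                                  else matrix(dirvec, 1), sp$prad),
                 score = sc, src = pid)
        }
      }
    }
  }
  if (!length(cand))
    return(probe_pool(probe_rows("steric", matrix(numeric(0), 0, 3),
                                 radius = numeric(0))[0, ], character(0)))
  probes <- do.call(rbind, lapply(cand, `[[`, "row"))
  scores <- vapply(cand, `[[`, numeric(1), "score")
  srcs <- vapply(cand, `[[`, character(1), "src")
  # same-type dedupe, better-scoring probe wins
  ord <- order(-scores)
  keep <- logical(length(ord))
  kept_by_type <- list()
  for (i in ord) {
    ty <- probes$type[i]
    pk <- kept_by_type[[ty]]
    pos <- c(probes$x[i], probes$y[i], probes$z[i])
    if (!is.null(pk)) {
      d2 <- (pk[, 1] - pos[1])^2 + (pk[, 2] - pos[2])^2 + (pk[, 3] - pos[3])^2
      if (any(d2 < config$dedupe_radius^2)) next
    }
    keep[i] <- TRUE
    kept_by_type[[ty]] <- rbind(pk, pos)
  }
  probe_pool(probes[keep, , drop = FALSE], srcs[keep], filtered = FALSE,
             score = scores[keep])
}

#' Filter a probe pool against protein pocket variants
#'
#' A steric probe is retained iff its center lies within `steric_tol`
#' (default 1.0 Angstrom) of a hydrophobic pocket atom of ANY variant; a
#' donor (acceptor) probe iff within `polar_tol` (default 2.0 Angstrom) of
#' a donor or donor_acceptor (acceptor or donor_acceptor) pocket atom of
#' ANY variant - a logical OR over the ensemble. Distances are
#' center-to-center; probe directions are untouched.
#'
#' @param pool a `pm_probepool`.
#' @param pockets nonempty list of `pm_pocket`, pre-aligned.
#' @param steric_tol,polar_tol retention distances (Angstrom).
#' @return the filtered `pm_probepool` (`filtered = TRUE`).
#' @export
filter_probes <- function(pool, pockets, steric_tol = 1.0, polar_tol = 2.0) {
  if (!length(pockets)) stop("empty pocket list")
  pr <- pool$probes
  if (!nrow(pr)) return(probe_pool(pr, character(0), filtered = TRUE))
  atoms <- do.call(rbind, lapply(pockets, function(pk)
    pk$atoms[!pk$atoms$is_hydrogen,
             c("interaction_class", "x", "y", "z"), drop = FALSE]))
  match_sets <- list(
    steric = c("hydrophobic"),
    donor = c("donor", "donor_acceptor"),
    acceptor = c("acceptor", "donor_acceptor"))
  tol <- c(steric = steric_tol, donor = polar_tol, acceptor = polar_tol)
  keep <- logical(nrow(pr))
  for (ty in names(match_sets)) {
    rows <- which(pr$type == ty)
    if (!length(rows)) next
    sel <- atoms$interaction_class %in% match_sets[[ty]]
    if (!any(sel)) next
    axyz <- t(as.matrix(atoms[sel, c("x", "y", "z")]))
    for (i in rows) {
      d2 <- colSums((axyz - c(pr$x[i], pr$y[i], pr$z[i]))^2)
      keep[i] <- min(d2) <= tol[[ty]]^2
    }
  }
  probe_pool(pr[keep, , drop = FALSE], pool$source_pose_ids[keep],
             filtered = TRUE,
             score = if (is.null(pool$score)) NULL else pool$score[keep])
}

#' Probe pool summary
#'
#' @param pool a `pm_probepool`.
#' @return list with counts by type, total, bounding box, and number
#'   density (probes per cubic Angstrom of bounding box).
#' @export
pool_stats <- function(pool) {
  pr <- pool$probes
  counts <- setNames(vapply(PROBE_TYPES, function(ty) sum(pr$type == ty),
                            numeric(1)), PROBE_TYPES)
  if (!nrow(pr))
    return(list(counts = counts, total = 0, bbox = NULL, density = NA_real_))
  bbox <- rbind(lo = c(min(pr$x), min(pr$y), min(pr$z)),
                hi = c(max(pr$x), max(pr$y), max(pr$z)))
  vol <- prod(pmax(bbox[2, ] - bbox[1, ], 1e-6))
  list(counts = counts, total = nrow(pr), bbox = bbox,
       density = nrow(pr) / vol)
}
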