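# Supervised pseudotime: a piecewise-linear candidate path on a 2-D
# embedding, orthogonal projection of nuclei, arc-length pseudotime.

#' Fit a candidate trajectory path on a 2-D embedding
#'
#' Builds a piecewise-linear path either through explicitly supplied
#' waypoints or through the per-group coordinate medians of
#' `ordered_groups` (in the stated order). An optional moving-average pass
#' smooths interior waypoints while preserving the endpoints.
#'
#' @param embedding Nucleus x 2 coordinate matrix with row names.
#' @param ordered_groups Character vector of group labels in trajectory
#'   order; requires `labels`.
#' @param labels Named vector mapping nucleus id to group.
#' @param waypoints Explicit waypoint matrix (n x 2); overrides groups.
#' @param smooth Integer window for moving-average smoothing (0 = none).
#' @return A `trajectory_path` object (waypoints, segment lengths,
#'   cumulative arc length).
#' @export
fit_path <- function(embedding, ordered_groups = NULL, labels = NULL,
                     waypoints = NULL, smooth = 0) {
  if (is.null(waypoints)) {
    if (is.null(ordered_groups) || is.null(labels)) {
      abort("supply either waypoints or ordered_groups + labels")
    }
    labels <- labels[rownames(embedding)]
    waypoints <- base::t(vapply(ordered_groups, function(g) {
      pts <- embedding[which(labels == g), , drop = FALSE]
      if (nrow(pts) == 0) abort(paste0("no nuclei labelled ", g))
      apply(pts, 2, median)
    }, numeric(2)))
  }
  waypoints <- as.matrix(waypoints)
  if (nrow(waypoints) < 2) abort("need at least 2 waypoints")
  if (smooth > 0 && nrow(waypoints) > 2) {
    inner <- waypoints
    for (i in seq(2, nrow(waypoints) - 1)) {
      lo <- max(1, i - smooth); hi <- min(nrow(waypoints), i + smooth)
      inner[i, ] <- colMeans(waypoints[lo:hi, , drop = FALSE])
    }
    waypoints <- inner
  }
  seg <- waypoints[-1, , drop = FALSE] - waypoints[-nrow(waypoints), ,
                                                   drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  if (any(lens == 0)) abort("coincident consecutive waypoints")
  structure(list(waypoints = unname(waypoints),
                 seg_lengths = lens,
                 cum_length = c(0, cumsum(lens)),
                 total_length = sum(lens)),
            class = "trajectory_path")
}

#' @export
print.trajectory_path <- function(x, ...) {
  cat(sprintf("<trajectory_path> %d waypoints, total arc length %.3f\n",
              nrow(x$waypoints), x$total_length))
  invisible(x)
}

# Project points onto a path; returns arc position and distance per point.
project_to_path <- function(points, path) {
  wp <- path$waypoints
  n_seg <- nrow(wp) - 1
  best_d2 <- rep(Inf, nrow(points))
  best_arc <- numeric(nrow(points))
  for (s in seq_len(n_seg)) {
    a <- wp[s, ]; b <- wp[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tpar <- ((points[, 1] - a[1]) * ab[1] + (points[, 2] - a[2]) * ab[2]) /
      len2
    tpar <- pmin(pmax(tpar, 0), 1)
    px <- a[1] + tpar * ab[1]
    py <- a[2] + tpar * ab[2]
    d2 <- (points[, 1] - px)^2 + (points[, 2] - py)^2
    upd <- d2 < best_d2 - 1e-15
    best_arc[upd] <- path$cum_length[s] + tpar[upd] * path$seg_lengths[s]
    best_d2[upd] <- d2[upd]
  }
  list(arc = best_arc, distance = sqrt(best_d2))
}

#' Assign arc-length pseudotime along a fitted path
#'
#' Each nucleus is orthogonally projected to its globally nearest path
#' segment; pseudotime is the cumulative arc length at the projection
#' divided by the total path length. The perpendicular distance is reported
#' for QC.
#'
#' @param embedding Nucleus x 2 coordinate matrix with row names.
#' @param path A [fit_path()] result.
#' @return Tibble (`nucleus`, `t`, `arc_length`, `distance`).
#' @export
assign_pseudotime <- function(embedding, path) {
  stopifnot(inherits(path, "trajectory_path"))
  pr <- project_to_path(as.matrix(embedding[, 1:2, drop = FALSE]), path)
  tibble(nucleus = rownames(embedding),
         t = pr$arc / path$total_length,
         arc_length = pr$arc,
         distance = pr$distance)
}

#' Branch-aware pseudotime on a bifurcating trajectory
#'
#' Branch paths must start at the root path's terminal waypoint. Each
#' nucleus is assigned to the branch whose root-plus-branch concatenation it
#' is closest to (perpendicular distance; exact ties break to the first
#' branch and are flagged), and pseudotime is computed on that
#' concatenation. Nuclei projecting onto the shared root get the root arc
#' position regardless of branch.
#'
#' @param embedding Nucleus x 2 matrix with row names.
#' @param root_path [fit_path()] result for the shared root.
#' @param branch_paths Named list of [fit_path()] results, each starting at
#'   the root's last waypoint.
#' @return Tibble (`nucleus`, `branch`, `t`, `arc_length`, `distance`,
#'   `tie`).
#' @export
branch_pseudotime <- function(embedding, root_path, branch_paths) {
  stopifnot(inherits(root_path, "trajectory_path"))
  root_end <- root_path$waypoints[nrow(root_path$waypoints), ]
  concat <- lapply(branch_paths, function(bp) {
    if (any(abs(bp$waypoints[1, ] - root_end) > 1e-9)) {
      abort("branch path does not start at the root's terminal waypoint")
    }
    fit_path(NULL, waypoints = rbind(root_path$waypoints,
                                     bp$waypoints[-1, , drop = FALSE]))
  })
  pts <- as.matrix(embedding[, 1:2, drop = FALSE])
  projs <- lapply(concat, function(p) project_to_path(pts, p))
  dmat <- vapply(projs, function(p) p$distance, numeric(nrow(pts)))
  dmat <- matrix(dmat, nrow = nrow(pts))
  best <- apply(dmat, 1, which.min)
  tie <- apply(dmat, 1, function(d) sum(abs(d - min(d)) < 1e-12) > 1)
  arc <- vapply(seq_len(nrow(pts)),
                function(i) projs[[best[i]]]$arc[i], numeric(1))
  dist <- vapply(seq_len(nrow(pts)),
                 function(i) projs[[best[i]]]$distance[i], numeric(1))
  total <- vapply(concat, function(p) p$total_length, numeric(1))
  tibble(nucleus = rownames(embedding),
         branch = names(branch_paths)[best],
         t = arc / total[best],
         arc_length = arc,
         distance = dist,
         tie = tie)
}
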