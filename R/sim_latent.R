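#' Simulate a shared latent space with a bifurcating trajectory
#'
#' Draws per-nucleus latent coordinates for both modalities from one common
#' process: a piecewise-linear trajectory (root segment then, when
#' `config$bifurcate`, two diverging branches) embedded in the first two
#' latent dimensions, plus isotropic Gaussian noise of sd `config$noise_sd`
#' in all dimensions. True pseudotime is the arc-length position along the
#' root-plus-assigned-branch path, normalized to \[0, 1\].
#'
#' @param config A [sim_config()].
#' @return A list with elements
#'   * `latent`: list of `rna` and `atac` nucleus x dim matrices,
#'   * `truth`: tibble (`nucleus`, `modality`, `true_pseudotime`,
#'     `true_branch`, `true_cluster`),
#'   * `paths`: list of 2-D waypoint matrices (`root`, and `A`, `B` or
#'     `main`) describing the generating trajectory.
#' @export
simulate_trajectory_latent <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$latent_dim < 2) abort("latent_dim must be >= 2")

  paths <- trajectory_geometry(config$bifurcate)

  draw_modality <- function(n, prefix, offset) {
    with_substream(config$seed, offset, {
      ids <- sprintf("%s_%04d", prefix, seq_len(n))
      branch_draw <- if (config$bifurcate) {
        sample(c("A", "B"), n, replace = TRUE)
      } else rep("main", n)
      u <- runif(n)
      pos <- t(vapply(seq_len(n), function(i) {
        point_on_concat_path(paths, branch_draw[i], u[i])
      }, numeric(2)))
      coords <- matrix(0, n, config$latent_dim)
      coords[, 1:2] <- pos
      coords <- coords + matrix(rnorm(n * config$latent_dim,
                                      sd = config$noise_sd),
                                n, config$latent_dim)
      rownames(coords) <- ids
      colnames(coords) <- paste0("dim", seq_len(config$latent_dim))
      # branch label is "root" before the bifurcation point
      root_len <- path_length(paths$root)
      totals <- root_len + vapply(branch_key(branch_draw), function(k) {
        path_length(paths[[k]])
      }, numeric(1))
      on_root <- u * totals <= root_len
      branch <- ifelse(on_root & config$bifurcate, "root", branch_draw)
      cluster <- assign_true_cluster(u, branch, config)
      list(coords = coords,
           truth = tibble(nucleus = ids,
                          modality = prefix,
                          true_pseudotime = u,
                          true_branch = branch,
                          true_cluster = cluster))
    })
  }

  rna <- draw_modality(config$n_rna_nuclei, "rna", 101L)
  atac <- draw_modality(config$n_atac_nuclei, "atac", 102L)

  list(latent = list(rna = rna$coords, atac = atac$coords),
       truth = bind_rows(rna$truth, atac$truth),
       paths = paths)
}

# Fixed trajectory geometry in the first two latent dimensions.
trajectory_geometry <- function(bifurcate) {
  root <- rbind(c(0, 0), c(3, 0))
  if (bifurcate) {
    list(root = root,
         A = rbind(c(3, 0), c(6, 2.4)),
         B = rbind(c(3, 0), c(6, -2.4)))
  } else {
    list(root = root, main = rbind(c(3, 0), c(6, 0)))
  }
}

branch_key <- function(branch) ifelse(branch %in% c("A", "B"), branch, "main")

path_length <- function(wp) {
  if (is.null(wp)) return(0)
  sum(sqrt(rowSums((wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE])^2)))
}

# Point at arc-length fraction u along root + branch concatenation.
point_on_concat_path <- function(paths, branch, u) {
  key <- if (branch %in% c("A", "B")) branch else "main"
  wp <- rbind(paths$root, paths[[key]][-1, , drop = FALSE])
  seg <- wp[-1, , drop = FALSE] - wp[-nrow(wp), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  total <- sum(lens)
  target <- u * total
  cum <- c(0, cumsum(lens))
  i <- max(which(cum <= target + 1e-12))
  i <- min(i, length(lens))
  frac <- if (lens[i] > 0) (target - cum[i]) / lens[i] else 0
  wp[i, ] + frac * seg[i, ]
}

# Cluster = root cluster before the split, then maturity bins per branch.
assign_true_cluster <- function(u, branch, config) {
  paths <- trajectory_geometry(config$bifurcate)
  root_len <- path_length(paths$root)
  if (!config$bifurcate) {
    bins <- pmin(config$n_clusters,
                 1L + floor(u * config$n_clusters))
    return(sprintf("c%d", bins))
  }
  n_branch_clusters <- config$n_clusters - 1L
  per_a <- ceiling(n_branch_clusters / 2)
  per_b <- n_branch_clusters - per_a
  total_a <- root_len + path_length(paths$A)
  out <- character(length(u))
  out[branch == "root"] <- "c1"
  for (b in c("A", "B")) {
    k <- if (b == "A") per_a else per_b
    idx <- which(branch == b)
    if (!length(idx) || k == 0) next
    total <- root_len + path_length(paths[[b]])
    # position along the branch segment only, in [0, 1]
    s <- (u[idx] * total - root_len) / path_length(paths[[b]])
    bin <- pmin(k, 1L + floor(pmax(s, 0) * k))
    base <- if (b == "A") 1L else 1L + per_a
    out[idx] <- sprintf("c%d", base + bin)
  }
  out
}
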