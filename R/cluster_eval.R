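# Stability-based partition selection over a resolution sweep, and internal
# cluster-quality indices.

# Canonical form of a partition: labels renamed in order of first
# appearance, so two partitions are equal up to renaming iff their
# canonical forms are identical.
canonical_partition <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Select the most frequent stable partition from a resolution sweep
#'
#' Groups the label vectors of a community-detection resolution sweep into
#' equivalence classes (identical up to label renaming, i.e. adjusted Rand
#' index 1; an optional `ari_tol` relaxes this) and returns a
#' representative of the most frequent class. Ties go to the class
#' containing the lowest resolution.
#'
#' @param ensemble Tibble (`resolution`, `nucleus`, `label`) or a named
#'   list of label vectors (names = resolutions), all over the same nuclei.
#' @param ari_tol Partitions with `ARI >= 1 - ari_tol` against a class
#'   representative join that class (default 0, exact equivalence).
#' @return List: `partition` (named label vector of the representative, the
#'   lowest-resolution member), `frequency` (class share), `classes`
#'   (tibble `resolution`, `class`).
#' @export
stability_select <- function(ensemble, ari_tol = 0) {
  if (is.data.frame(ensemble)) {
    parts <- lapply(split(ensemble, ensemble$resolution), function(d) {
      setNames(d$label, d$nucleus)
    })
  } else {
    parts <- ensemble
  }
  if (length(parts) < 2) abort("need at least 2 partitions")
  nuclei <- sort(names(parts[[1]]))
  for (p in parts) {
    if (!identical(sort(names(p)), nuclei)) {
      abort("partitions cover different nucleus sets")
    }
  }
  resolutions <- names(parts)
  ord <- order(suppressWarnings(as.numeric(resolutions)), resolutions)
  parts <- parts[ord]
  resolutions <- resolutions[ord]

  canon <- lapply(parts, function(p) canonical_partition(p[nuclei]))
  class_of <- integer(length(parts))
  reps <- list()
  for (i in seq_along(parts)) {
    assigned <- FALSE
    for (k in seq_along(reps)) {
      same <- if (ari_tol <= 0) {
        identical(canon[[i]], reps[[k]])
      } else {
        mclust::adjustedRandIndex(canon[[i]], reps[[k]]) >= 1 - ari_tol
      }
      if (same) { class_of[i] <- k; assigned <- TRUE; break }
    }
    if (!assigned) {
      reps[[length(reps) + 1L]] <- canon[[i]]
      class_of[i] <- length(reps)
    }
  }
  freq <- table(class_of)
  best_class <- as.integer(names(freq)[freq == max(freq)])
  # ties: the class containing the lowest resolution (parts are ordered)
  chosen <- min(vapply(best_class, function(k) min(which(class_of == k)),
                       integer(1)))
  chosen_class <- class_of[chosen]
  list(partition = parts[[chosen]][nuclei],
       frequency = max(freq) / length(parts),
       classes = tibble(resolution = resolutions,
                        class = class_of))
}

#' Dunn index of a labeled point set
#'
#' Minimum inter-cluster point distance divided by the maximum intra-cluster
#' diameter. When every cluster is a singleton (zero maximum diameter) the
#' index is `Inf`.
#'
#' @param points Numeric matrix (points x dims) or vector.
#' @param labels Cluster label per point (>= 2 clusters).
#' @return Scalar Dunn index.
#' @export
dunn_index <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) abort("Dunn index needs >= 2 clusters")
  d <- as.matrix(dist(points))
  same <- outer(labels, labels, "==")
  diag(same) <- NA
  inter <- min(d[!same & !is.na(same)])
  intra <- d[same & !is.na(same)]
  max_diam <- if (length(intra)) max(intra) else 0
  if (max_diam == 0) return(Inf)
  inter / max_diam
}

#' Mean silhouette coefficient
#'
#' Standard silhouette: per point, `a` the mean distance to its own
#' cluster's other points, `b` the smallest mean distance to another
#' cluster, `s = (b - a) / max(a, b)`. Points in singleton clusters score 0
#' by convention.
#'
#' @param points Numeric matrix (points x dims) or vector.
#' @param labels Cluster label per point (>= 2 clusters).
#' @return Mean silhouette, in \[-1, 1\].
#' @export
silhouette_mean <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.character(labels)
  clusters <- unique(labels)
  if (length(clusters) < 2) abort("silhouette needs >= 2 clusters")
  d <- as.matrix(dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(clusters, labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
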