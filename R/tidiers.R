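# broom-style tidiers for the package's fitted objects.

#' Tidy a trajectory path
#'
#' @param x A `trajectory_path`.
#' @param ... Unused.
#' @return Tibble (`waypoint`, `x`, `y`, `arc_length`).
#' @export
tidy.trajectory_path <- function(x, ...) {
  wp <- x$waypoints
  cl <- x$cum_length
  tibble(waypoint = seq_len(nrow(wp)),
         x = wp[, 1], y = wp[, 2],
         arc_length = cl)
}

#' @rdname tidy.trajectory_path
#' @return `glance()`: one-row tibble (`n_waypoints`, `n_segments`,
#'   `total_length`).
#' @export
glance.trajectory_path <- function(x, ...) {
  tibble(n_waypoints = nrow(x$waypoints),
         n_segments = length(x$seg_lengths),
         total_length = x$total_length)
}

#' Tidy a regulatory network
#'
#' One row per edge of the tripartite graph.
#'
#' @param x An `egrn`.
#' @param ... Unused.
#' @return Tibble (`cluster`, `source`, `interaction`, `target`, `weight`).
#' @export
tidy.egrn <- function(x, ...) {
  bind_rows(
    tibble(cluster = x$tf_element$cluster, source = x$tf_element$tf_gene,
           interaction = "binds", target = x$tf_element$peak_id,
           weight = x$tf_element$nes),
    tibble(cluster = x$element_gene$cluster,
           source = x$element_gene$peak_id, interaction = "links",
           target = x$element_gene$gene_id,
           weight = x$element_gene$link_r)
  )
}

#' @rdname tidy.egrn
#' @return `glance()`: one-row tibble with node and edge counts.
#' @export
glance.egrn <- function(x, ...) {
  tibble(n_tfs = nrow(x$tfs), n_elements = nrow(x$elements),
         n_genes = nrow(x$genes),
         n_tf_element_edges = nrow(x$tf_element),
         n_element_gene_edges = nrow(x$element_gene))
}
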