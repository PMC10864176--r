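# ggplot2 visualisations for the main result types.

#' Plot pseudotime over a 2-D embedding
#'
#' @param embedding Nucleus x 2 matrix with row names.
#' @param pseudotime Tibble from [assign_pseudotime()] or
#'   [branch_pseudotime()].
#' @return A ggplot object.
#' @export
plot_pseudotime <- function(embedding, pseudotime) {
  df <- tibble(nucleus = rownames(embedding),
               x = embedding[, 1], y = embedding[, 2]) |>
    left_join(pseudotime, by = "nucleus")
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$t)) +
    geom_point(size = 0.8) +
    scale_colour_viridis_c(name = "pseudotime") +
    labs(x = "dim 1", y = "dim 2") +
    theme_minimal()
}

#' @export
autoplot.trajectory_path <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x, y = .data$y)) +
    geom_path(colour = "grey40") +
    geom_point(colour = "firebrick") +
    labs(x = "dim 1", y = "dim 2") +
    theme_minimal()
}

#' Distance-vs-correlation view of a link table
#'
#' @param links Link tibble from [filter_links()].
#' @return A ggplot object.
#' @export
plot_links <- function(links) {
  ggplot(links, aes(x = .data$distance / 1000, y = .data$r,
                    colour = .data$accepted)) +
    geom_point(alpha = 0.6, size = 0.8) +
    labs(x = "peak midpoint - TSS (kb)", y = "Pearson r",
         colour = "accepted") +
    theme_minimal()
}

#' Dot plot of motif NES by cluster
#'
#' @param enrichment Tibble from [motif_enrichment()] or
#'   [merge_enrichments()].
#' @return A ggplot object.
#' @export
plot_nes <- function(enrichment) {
  ggplot(enrichment, aes(x = .data$cluster, y = .data$motif_id,
                         size = .data$nes, colour = .data$nes)) +
    geom_point() +
    scale_colour_viridis_c(name = "NES") +
    labs(x = "cluster", y = "motif") +
    theme_minimal()
}

#' @export
autoplot.egrn <- function(object, ...) {
  g <- egrn_igraph(object)
  set.seed(1)
  lay <- igraph::layout_with_fr(g)
  df <- tibble(name = igraph::V(g)$name, type = igraph::V(g)$type,
               x = lay[, 1], y = lay[, 2])
  ed <- igraph::as_data_frame(g, what = "edges") |>
    left_join(df, by = c(from = "name")) |>
    rename(x0 = "x", y0 = "y") |>
    left_join(df, by = c(to = "name"))
  ggplot() +
    geom_segment(data = ed, aes(x = .data$x0, y = .data$y0,
                                xend = .data$x, yend = .data$y),
                 colour = "grey70", linewidth = 0.3) +
    geom_point(data = df, aes(x = .data$x, y = .data$y,
                              colour = .data$type), size = 2) +
    labs(colour = NULL, x = NULL, y = NULL) +
    theme_minimal()
}
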