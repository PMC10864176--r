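# TF mining: cisTarget-style recovery-AUC/NES motif enrichment on DAR sets,
# NES-vs-expression correlation ranking, regulator selection, and assembly
# of the tripartite TF -> cis-element -> target-gene network.

#' Per-motif peak rankings from a motif score table
#'
#' For each motif, ranks all peaks by descending motif score (peaks without
#' a hit score 0), breaking ties by peak coordinate and then peak id so the
#' ranking is fully deterministic.
#'
#' @param motif_scores Tibble (`peak_id`, `motif_id`, `score`).
#' @param peaks Tibble (`peak_id`, `chrom`, `start`, `end`) defining the
#'   full peak universe and the coordinate tie-break.
#' @return Named list: per motif, the character vector of peak ids from best
#'   to worst rank.
#' @export
motif_rankings <- function(motif_scores, peaks) {
  if (anyDuplicated(peaks$peak_id)) abort("duplicate peak ids")
  if (any(!is.finite(motif_scores$score))) abort("non-finite motif scores")
  base <- peaks[order(peaks$chrom, peaks$start, peaks$end, peaks$peak_id), ]
  motifs <- sort(unique(motif_scores$motif_id))
  score_mat <- matrix(0, nrow(base), length(motifs),
                      dimnames = list(base$peak_id, motifs))
  idx <- cbind(match(motif_scores$peak_id, base$peak_id),
               match(motif_scores$motif_id, motifs))
  if (anyNA(idx[, 1])) abort("motif hit refers to an unknown peak id")
  score_mat[idx] <- motif_scores$score
  lapply(setNames(motifs, motifs), function(m) {
    # order() is stable, so coordinate order decides ties
    base$peak_id[order(-score_mat[, m])]
  })
}

#' Recovery AUC of a region set along a motif ranking
#'
#' Walks down the ranking accumulating the fraction of the region set
#' recovered, and averages that recovery over the top
#' `max(ceiling(auc_fraction * N), min_top)` ranks — the truncated
#' recovery-curve AUC, normalized to \[0, 1\].
#'
#' @param ranking Character vector of peak ids, best first.
#' @param region_set Character vector of peak ids (subset of the ranking).
#' @param auc_fraction Top fraction of the ranking integrated (default
#'   0.001).
#' @param min_top Floor on the number of integrated ranks (default 20), so
#'   small peak universes keep a meaningful window.
#' @return Scalar AUC in \[0, 1\].
#' @export
recovery_auc <- function(ranking, region_set, auc_fraction = 0.001,
                         min_top = 20) {
  region_set <- unique(region_set)
  if (length(region_set) == 0) abort("empty region set")
  if (!all(region_set %in% ranking)) {
    abort("region_set contains peaks absent from the ranking")
  }
  top_n <- min(length(ranking), max(ceiling(auc_fraction * length(ranking)),
                                    min_top))
  hits <- ranking[seq_len(top_n)] %in% region_set
  recovery <- cumsum(hits) / length(region_set)
  mean(recovery)
}

#' Normalized enrichment scores from per-motif AUCs
#'
#' The NES of a motif is the z-score of its AUC against all motifs scored
#' for the same region set: `(AUC - mean) / sd`.
#'
#' @param aucs Named numeric vector of per-motif AUCs (>= 3 motifs).
#' @return Named numeric vector of NES values (mean 0, sd 1).
#' @export
nes_scores <- function(aucs) {
  if (length(aucs) < 3) abort("need at least 3 motifs to normalize")
  s <- sd(aucs)
  if (s == 0) abort("zero standard deviation across motif AUCs")
  (aucs - mean(aucs)) / s
}

#' Motif enrichment of cluster region sets
#'
#' Runs the full recovery-AUC/NES scan: per cluster, ranks peaks per motif,
#' computes each motif's recovery AUC of the cluster's region set (its
#' DARs), and normalizes to NES across motifs.
#'
#' @param motif_scores Tibble (`peak_id`, `motif_id`, `score`).
#' @param peaks Peak universe tibble (see [motif_rankings()]).
#' @param region_sets Named list: per cluster, character vector of peak ids.
#' @param motif_truth Tibble (`motif_id`, `tf_gene`) assigning each motif a
#'   TF gene.
#' @param auc_fraction,min_top Passed to [recovery_auc()].
#' @param source Label recorded in the `source` column (default
#'   `"recovery_auc"`).
#' @return Motif-enrichment tibble (`cluster`, `motif_id`, `tf_gene`,
#'   `auc`, `nes`, `source`).
#' @export
motif_enrichment <- function(motif_scores, peaks, region_sets, motif_truth,
                             auc_fraction = 0.001, min_top = 20,
                             source = "recovery_auc") {
  rankings <- motif_rankings(motif_scores, peaks)
  rows <- lapply(names(region_sets), function(cl) {
    rs <- intersect(region_sets[[cl]], peaks$peak_id)
    if (!length(rs)) return(NULL)
    aucs <- vapply(rankings, recovery_auc, numeric(1),
                   region_set = rs, auc_fraction = auc_fraction,
                   min_top = min_top)
    nes <- nes_scores(aucs)
    tibble(cluster = cl, motif_id = names(aucs), auc = unname(aucs),
           nes = unname(nes), source = source)
  })
  out <- bind_rows(rows)
  left_join(out, motif_truth, by = "motif_id") |>
    select("cluster", "motif_id", "tf_gene", "auc", "nes", "source")
}

#' Merge motif-enrichment tables from several sources
#'
#' Per (cluster, motif), keeps the maximal NES across sources, then drops
#' motifs below the NES floor (default 3.0).
#'
#' @param tables List of motif-enrichment tibbles (from
#'   [motif_enrichment()] or equivalent) sharing a motif-to-TF assignment.
#' @param nes_floor Minimal NES retained (default 3; use `-Inf` to keep
#'   everything, e.g. when feeding [tf_expression_correlation()]).
#' @return Merged tibble (`cluster`, `motif_id`, `tf_gene`, `auc`, `nes`,
#'   `source`).
#' @export
merge_enrichments <- function(tables, nes_floor = 3) {
  all_tbl <- bind_rows(tables)
  conflict <- all_tbl |>
    distinct(.data$motif_id, .data$tf_gene) |>
    dplyr::count(.data$motif_id) |>
    filter(.data$n > 1)
  if (nrow(conflict)) {
    abort(paste0("conflicting TF assignment for motif(s): ",
                 paste(conflict$motif_id, collapse = ", ")))
  }
  all_tbl |>
    group_by(.data$cluster, .data$motif_id, .data$tf_gene) |>
    arrange(desc(.data$nes)) |>
    slice(1) |>
    ungroup() |>
    filter(.data$nes >= nes_floor) |>
    arrange(.data$cluster, desc(.data$nes))
}

#' Correlate TF motif NES with TF gene expression across clusters
#'
#' A TF regulator is taken seriously only when its motif enrichment tracks
#' its own expression: per TF, the Pearson correlation across clusters
#' between the NES vector and the mean-expression vector, ranked descending.
#'
#' @param nes_by_cluster Tibble (`cluster`, `tf_gene`, `nes`); typically the
#'   unfloored merge of enrichment tables (max NES per cluster/TF).
#' @param expr_by_cluster Tibble (`cluster`, `tf_gene`, `mean_expr`).
#' @return Tibble (`tf_gene`, `r`, `n_clusters`, `rank`), constant-vector
#'   TFs dropped with a warning.
#' @export
tf_expression_correlation <- function(nes_by_cluster, expr_by_cluster) {
  joined <- inner_join(nes_by_cluster, expr_by_cluster,
                       by = c("cluster", "tf_gene"))
  if (dplyr::n_distinct(joined$cluster) < 3) {
    abort("need at least 3 clusters to correlate NES with expression")
  }
  out <- joined |>
    group_by(.data$tf_gene) |>
    summarise(
      n_clusters = dplyr::n(),
      constant = sd(.data$nes) == 0 || sd(.data$mean_expr) == 0,
      r = if (constant[1]) NA_real_ else cor(.data$nes, .data$mean_expr),
      .groups = "drop"
    )
  dropped <- filter(out, .data$constant | .data$n_clusters < 3)
  if (nrow(dropped)) {
    warn(paste0("dropping TF(s) with constant or short vectors: ",
                paste(dropped$tf_gene, collapse = ", ")))
  }
  out |>
    filter(!.data$constant, .data$n_clusters >= 3) |>
    select("tf_gene", "r", "n_clusters") |>
    arrange(desc(.data$r)) |>
    mutate(rank = row_number())
}

#' Select cluster-specific TF regulators
#'
#' Per cluster: TFs whose motif passes the NES floor in that cluster and
#' whose NES-expression correlation is positive, keeping the top
#' `per_cluster_top` by correlation.
#'
#' @param corr_ranked Tibble from [tf_expression_correlation()].
#' @param nes_table Floored enrichment tibble from [merge_enrichments()].
#' @param per_cluster_top Regulators retained per cluster (default 5).
#' @return Tibble (`cluster`, `tf_gene`, `motif_id`, `nes`, `r`).
#' @export
select_regulators <- function(corr_ranked, nes_table, per_cluster_top = 5) {
  nes_table |>
    inner_join(select(corr_ranked, "tf_gene", "r"), by = "tf_gene") |>
    filter(.data$r > 0) |>
    group_by(.data$cluster) |>
    arrange(desc(.data$r), desc(.data$nes)) |>
    slice(seq_len(min(dplyr::n(), per_cluster_top))) |>
    ungroup() |>
    select("cluster", "tf_gene", "motif_id", "nes", "r")
}

#' Assemble the TF -> cis-element -> target-gene network
#'
#' For each selected TF in a cluster, the cis-element nodes are the peaks
#' that are simultaneously (1) DARs of that cluster, (2) carriers of the
#' TF's motif, and (3) present in the accepted peak-to-gene links; target
#' genes are the genes those elements link to, so every TF -> element ->
#' gene path is complete.
#'
#' @param selected Tibble from [select_regulators()].
#' @param motif_hits Tibble (`peak_id`, `motif_id`, `score`).
#' @param dars Tibble (`peak_id`, `group`) of per-cluster DARs (groups must
#'   use the same cluster labels as `selected`).
#' @param links Accepted link tibble (`peak_id`, `gene_id`, `r`, ...).
#' @return An `egrn` object: tibbles `tf_element` and `element_gene` plus
#'   node tables; see also [export_network()], [tidy.egrn()].
#' @export
assemble_egrn <- function(selected, motif_hits, dars, links) {
  acc <- if ("accepted" %in% names(links)) {
    filter(links, .data$accepted)
  } else links
  unknown_motif <- setdiff(selected$motif_id, unique(motif_hits$motif_id))
  if (length(unknown_motif)) {
    abort(paste0("selected motif absent from motif hits: ", unknown_motif[1]))
  }

  tf_rows <- list(); eg_rows <- list()
  for (i in seq_len(nrow(selected))) {
    cl <- selected$cluster[i]
    tf <- selected$tf_gene[i]
    mot <- selected$motif_id[i]
    cl_dars <- dars$peak_id[dars$group == cl]
    mot_peaks <- motif_hits$peak_id[motif_hits$motif_id == mot]
    elements <- Reduce(intersect, list(cl_dars, mot_peaks,
                                       unique(acc$peak_id)))
    if (!length(elements)) next
    el_links <- filter(acc, .data$peak_id %in% elements)
    tf_rows[[i]] <- tibble(cluster = cl, tf_gene = tf, motif_id = mot,
                           peak_id = unique(el_links$peak_id),
                           nes = selected$nes[i], tf_corr = selected$r[i])
    eg_rows[[i]] <- tibble(cluster = cl, tf_gene = tf,
                           peak_id = el_links$peak_id,
                           gene_id = el_links$gene_id,
                           link_r = el_links$r)
  }
  empty_te <- tibble(cluster = character(), tf_gene = character(),
                     motif_id = character(), peak_id = character(),
                     nes = numeric(), tf_corr = numeric())
  empty_eg <- tibble(cluster = character(), tf_gene = character(),
                     peak_id = character(), gene_id = character(),
                     link_r = numeric())
  tf_element <- bind_rows(empty_te, tf_rows)
  element_gene <- bind_rows(empty_eg, eg_rows)
  structure(
    list(tf_element = tf_element,
         element_gene = element_gene,
         tfs = distinct(tf_element, .data$cluster, .data$tf_gene,
                        .data$motif_id, .data$nes, .data$tf_corr),
         elements = distinct(element_gene, .data$peak_id),
         genes = distinct(element_gene, .data$gene_id)),
    class = "egrn"
  )
}

#' @export
print.egrn <- function(x, ...) {
  cat("<egrn>\n")
  cat(sprintf("  %d TF nodes, %d cis-elements, %d target genes\n",
              nrow(x$tfs), nrow(x$elements), nrow(x$genes)))
  cat(sprintf("  %d TF->element edges, %d element->gene edges\n",
              nrow(x$tf_element), nrow(x$element_gene)))
  invisible(x)
}

#' Export / import a regulatory network
#'
#' Writes `edges.tsv` (source, interaction, target, attributes),
#' `nodes.tsv` and a `network.sif`; [import_network()] reproduces the graph
#' exactly.
#'
#' @param network An `egrn` from [assemble_egrn()].
#' @param dir Output directory.
#' @return `dir` invisibly; `import_network()` returns an `egrn`.
#' @export
export_network <- function(network, dir) {
  stopifnot(inherits(network, "egrn"))
  if (nrow(network$tfs) == 0) abort("empty network: no TF nodes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- bind_rows(
    network$tf_element |>
      mutate(source = .data$tf_gene, interaction = "binds",
             target = .data$peak_id, attr1 = .data$nes,
             attr2 = .data$tf_corr) |>
      select("source", "interaction", "target", "cluster", "motif_id",
             "attr1", "attr2"),
    network$element_gene |>
      mutate(source = .data$peak_id, interaction = "links",
             target = .data$gene_id, attr1 = .data$link_r,
             attr2 = NA_real_, motif_id = NA_character_) |>
      select("source", "interaction", "target", "cluster", "motif_id",
             "attr1", "attr2")
  )
  readr::write_tsv(edges, file.path(dir, "edges.tsv"))
  nodes <- bind_rows(
    network$tfs |> mutate(node = .data$tf_gene, type = "tf") |>
      select("node", "type", "cluster"),
    network$elements |> mutate(node = .data$peak_id, type = "cis_element",
                               cluster = NA_character_) |>
      select("node", "type", "cluster"),
    network$genes |> mutate(node = .data$gene_id, type = "target_gene",
                            cluster = NA_character_) |>
      select("node", "type", "cluster")
  ) |> distinct()
  readr::write_tsv(nodes, file.path(dir, "nodes.tsv"))
  sif <- paste(edges$source, edges$interaction, edges$target)
  readr::write_lines(sif, file.path(dir, "network.sif"))
  invisible(dir)
}

#' @rdname export_network
#' @export
import_network <- function(dir) {
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           show_col_types = FALSE)
  te <- filter(edges, .data$interaction == "binds") |>
    mutate(tf_gene = .data$source, peak_id = .data$target,
           nes = .data$attr1, tf_corr = .data$attr2) |>
    select("cluster", "tf_gene", "motif_id", "peak_id", "nes", "tf_corr")
  eg <- filter(edges, .data$interaction == "links") |>
    mutate(peak_id = .data$source, gene_id = .data$target,
           link_r = .data$attr1) |>
    select("cluster", "peak_id", "gene_id", "link_r")
  # recover tf_gene on element->gene rows through the binds edges
  eg <- left_join(eg, distinct(te, .data$cluster, .data$tf_gene,
                               .data$peak_id),
                  by = c("cluster", "peak_id"),
                  relationship = "many-to-many") |>
    select("cluster", "tf_gene", "peak_id", "gene_id", "link_r")
  structure(
    list(tf_element = te,
         element_gene = eg,
         tfs = distinct(te, .data$cluster, .data$tf_gene, .data$motif_id,
                        .data$nes, .data$tf_corr),
         elements = distinct(eg, .data$peak_id),
         genes = distinct(eg, .data$gene_id)),
    class = "egrn"
  )
}

#' Convert an `egrn` to an igraph object
#'
#' @param network An `egrn`.
#' @return An `igraph` directed graph with `type` vertex attribute.
#' @export
egrn_igraph <- function(network) {
  stopifnot(inherits(network, "egrn"))
  edges <- bind_rows(
    tibble(from = network$tf_element$tf_gene,
           to = network$tf_element$peak_id),
    tibble(from = network$element_gene$peak_id,
           to = network$element_gene$gene_id)
  ) |> distinct()
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  type <- rep("cis_element", igraph::vcount(g))
  nm <- igraph::V(g)$name
  type[nm %in% network$tfs$tf_gene] <- "tf"
  type[nm %in% network$genes$gene_id] <- "target_gene"
  igraph::V(g)$type <- type
  g
}
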