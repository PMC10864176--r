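# Marker/differential testing: Wilcoxon group-vs-rest markers, ANOVA
# markers, three-method top-N consensus, Welch-t DARs, Fisher enrichment.

log2_fc <- function(mean1, mean2, eps = 1e-9) {
  log2((mean1 + eps) / (mean2 + eps))
}

rank_marker_table <- function(tbl) {
  tbl |>
    arrange(.data$group, .data$p, desc(abs(.data$log2FC)), .data$feature) |>
    group_by(.data$group) |>
    mutate(rank = row_number()) |>
    ungroup()
}

#' Wilcoxon rank-sum markers (group vs rest)
#'
#' For every feature and group, tests the group's normalized values against
#' all other nuclei with the Wilcoxon rank-sum test (normal approximation
#' with tie correction; exact when both sides are small and tie-free).
#' Features are kept when the fraction of nuclei with nonzero signal reaches
#' `min_pct` on at least one side and the log2 fold change (computed on the
#' `expm1` scale of the normalized values) reaches `logfc_min`.
#'
#' @param norm_counts Feature x nucleus matrix of normalized log1p values.
#' @param labels Named vector mapping nucleus to group.
#' @param min_pct Minimum detection fraction on either side (default 0.1).
#' @param logfc_min Minimum log2 fold change (default 0.25).
#' @return Marker tibble (`feature`, `group`, `log2FC`, `pct_in`,
#'   `pct_out`, `p`, `q`, `rank`), BH-adjusted within group.
#' @export
wilcoxon_markers <- function(norm_counts, labels, min_pct = 0.1,
                             logfc_min = 0.25) {
  mat <- as.matrix(norm_counts)
  labels <- labels[colnames(mat)]
  groups <- sort(unique(labels))
  if (length(groups) < 2) abort("need at least 2 groups")

  rows <- list()
  for (g in groups) {
    in_g <- labels == g
    if (sum(in_g) < 2) {
      warn(paste0("group ", g, " has fewer than 2 nuclei; skipped"))
      next
    }
    pct_in <- rowMeans(mat[, in_g, drop = FALSE] > 0)
    pct_out <- rowMeans(mat[, !in_g, drop = FALSE] > 0)
    mean_in <- rowMeans(expm1(mat[, in_g, drop = FALSE]))
    mean_out <- rowMeans(expm1(mat[, !in_g, drop = FALSE]))
    lfc <- log2_fc(mean_in, mean_out)
    keep <- (pct_in >= min_pct | pct_out >= min_pct) & lfc >= logfc_min
    keep[is.na(keep)] <- FALSE
    feats <- rownames(mat)[keep]
    if (!length(feats)) next
    p <- vapply(feats, function(f) {
      suppressWarnings(
        wilcox.test(mat[f, in_g], mat[f, !in_g], exact = NULL)$p.value
      )
    }, numeric(1))
    rows[[g]] <- tibble(feature = feats, group = g,
                        log2FC = unname(lfc[keep]),
                        pct_in = unname(pct_in[keep]),
                        pct_out = unname(pct_out[keep]),
                        p = unname(p))
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(feature = character(), group = character(),
                  log2FC = numeric(), pct_in = numeric(),
                  pct_out = numeric(), p = numeric(), q = numeric(),
                  rank = integer()))
  }
  out <- out |> group_by(.data$group) |>
    mutate(q = bh_adjust(.data$p)) |> ungroup()
  rank_marker_table(out)
}

#' One-way ANOVA markers across groups
#'
#' Per feature, a one-way ANOVA F-test across all groups; a feature is
#' reported for its best group (highest mean) and kept when `p < p_max` and
#' the absolute log2 fold change of that group against the rest exceeds
#' `fc_min`. Features with zero variance everywhere are flagged (`p = NA`),
#' not dropped with an error.
#'
#' @param norm_counts Feature x nucleus matrix of normalized values.
#' @param labels Named vector mapping nucleus to group.
#' @param fc_min Minimum |log2 fold change| of the focal group vs rest
#'   (default 0.5).
#' @param p_max ANOVA p-value cutoff (default 0.05).
#' @return Marker tibble as in [wilcoxon_markers()] (without pct columns).
#' @export
anova_markers <- function(norm_counts, labels, fc_min = 0.5, p_max = 0.05) {
  mat <- as.matrix(norm_counts)
  labels <- labels[colnames(mat)]
  g <- factor(labels)
  if (nlevels(g) < 2) abort("need at least 2 groups")

  res <- lapply(rownames(mat), function(f) {
    x <- mat[f, ]
    p <- if (all(vapply(split(x, g), function(v) var(v) == 0, logical(1)))) {
      NA_real_
    } else {
      tryCatch(oneway.test(x ~ g, var.equal = TRUE)$p.value,
               error = function(e) NA_real_)
    }
    means <- vapply(split(x, g), mean, numeric(1))
    focal <- names(which.max(means))
    lfc <- log2_fc(mean(x[g == focal]), mean(x[g != focal]))
    tibble(feature = f, group = focal, log2FC = lfc, p = p)
  })
  out <- bind_rows(res) |>
    mutate(flagged = is.na(.data$p)) |>
    filter(.data$flagged | (.data$p < p_max & abs(.data$log2FC) > fc_min))
  out <- out |> mutate(q = bh_adjust(.data$p))
  rank_marker_table(filter(out, !.data$flagged)) |>
    bind_rows(filter(out, .data$flagged) |> mutate(rank = NA_integer_))
}

#' Shared top-N consensus across marker tables
#'
#' Intersects the top `top_n` features of each table under that table's own
#' rank order — the three-method consensus used to call robust DEGs.
#'
#' @param tables List of marker tibbles carrying `feature` and `rank`
#'   columns (one rank order per table; tables may be pre-filtered to one
#'   group).
#' @param top_n Depth of each list (default 200).
#' @return Character vector of shared features.
#' @export
consensus_top200 <- function(tables, top_n = 200) {
  if (length(tables) < 2) abort("need at least 2 marker tables")
  tops <- lapply(tables, function(tb) {
    tb <- arrange(tb, .data$rank)
    if (nrow(tb) < top_n) {
      warn("marker table shorter than top_n; using the full table")
    }
    head(tb$feature, top_n)
  })
  Reduce(intersect, tops)
}

#' Differentially accessible regions by Welch t-test
#'
#' Per group, tests each peak's per-nucleus raw counts (group vs rest) with
#' the unequal-variance t-test, keeps peaks with `p < p_max` and
#' `log2FC >= log2fc_min` (raw group means), and truncates to the `top_k`
#' best-ranked peaks.
#'
#' @param peak_counts Peak x nucleus raw count matrix.
#' @param labels Named vector mapping nucleus to group.
#' @param p_max P-value cutoff (default 0.001).
#' @param log2fc_min Minimum log2 fold change (default 1).
#' @param top_k Maximum DARs kept per group (default 5000).
#' @return Tibble (`peak_id`, `group`, `log2FC`, `p`, `rank`).
#' @export
dar_ttest <- function(peak_counts, labels, p_max = 0.001, log2fc_min = 1,
                      top_k = 5000) {
  mat <- as.matrix(peak_counts)
  labels <- labels[colnames(mat)]
  groups <- sort(unique(labels))
  rows <- list()
  for (g in groups) {
    in_g <- labels == g
    if (sum(in_g) < 2) {
      warn(paste0("group ", g, " has fewer than 2 nuclei; skipped"))
      next
    }
    mean_in <- rowMeans(mat[, in_g, drop = FALSE])
    mean_out <- rowMeans(mat[, !in_g, drop = FALSE])
    lfc <- log2_fc(mean_in, mean_out)
    p <- apply(mat, 1, function(x) {
      tryCatch(t.test(x[in_g], x[!in_g])$p.value,
               error = function(e) NA_real_)
    })
    keep <- !is.na(p) & p < p_max & lfc >= log2fc_min
    if (!any(keep)) next
    tb <- tibble(peak_id = rownames(mat)[keep], group = g,
                 log2FC = unname(lfc[keep]), p = unname(p[keep])) |>
      arrange(.data$p, desc(abs(.data$log2FC)), .data$peak_id) |>
      mutate(rank = row_number()) |>
      slice(seq_len(min(dplyr::n(), top_k)))
    rows[[g]] <- tb
  }
  bind_rows(rows)
}

#' One-sided Fisher (hypergeometric) set enrichment
#'
#' Per term set, the upper-tail hypergeometric p-value of the overlap
#' between the query and the term within the universe, with BH adjustment
#' across terms — the generic one-sided Fisher exact enrichment test.
#'
#' @param query Character vector, a subset of `universe`.
#' @param term_sets Named list of character vectors (each a subset of
#'   `universe`).
#' @param universe Character vector of all testable features.
#' @return Tibble (`term`, `n_query`, `n_term`, `n_overlap`, `odds_ratio`,
#'   `p`, `q`) sorted by `p`.
#' @export
fisher_enrichment <- function(query, term_sets, universe) {
  query <- unique(query)
  if (length(query) == 0) abort("empty query set")
  if (!all(query %in% universe)) abort("query must be a subset of universe")
  N <- length(unique(universe))
  n_q <- length(query)
  rows <- lapply(names(term_sets), function(tm) {
    term <- intersect(unique(term_sets[[tm]]), universe)
    k <- length(intersect(query, term))
    K <- length(term)
    p <- phyper(k - 1, K, N - K, n_q, lower.tail = FALSE)
    or <- (k * (N - K - n_q + k)) / max((K - k) * (n_q - k), .Machine$double.eps)
    tibble(term = tm, n_query = n_q, n_term = K, n_overlap = k,
           odds_ratio = or, p = p)
  })
  out <- bind_rows(rows)
  out$q <- bh_adjust(out$p)
  arrange(out, .data$p)
}
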