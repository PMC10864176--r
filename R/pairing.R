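#' Pair ATAC nuclei to RNA nuclei in a shared latent space
#'
#' For every ATAC nucleus, finds the RNA nucleus at minimal Euclidean
#' distance in the shared embedding (exact search; ties broken by lowest RNA
#' column index). Many ATAC nuclei may map to the same RNA nucleus.
#'
#' @param atac,rna Nucleus x dim embedding matrices with row names; both
#'   must share the latent dimension.
#' @return Tibble (`atac_nucleus`, `rna_nucleus`, `distance`).
#' @export
pair_nuclei <- function(atac, rna) {
  if (ncol(atac) != ncol(rna)) {
    abort("latent dimension mismatch between modalities")
  }
  if (nrow(rna) == 0) abort("rna embedding is empty")
  if (is.null(rownames(atac)) || is.null(rownames(rna))) {
    abort("embeddings must carry nucleus ids as row names")
  }
  # squared distances via the expansion |a - r|^2 = |a|^2 + |r|^2 - 2 a.r
  cross <- atac %*% base::t(rna)
  d2 <- sweep(sweep(-2 * cross, 2, rowSums(rna^2), "+"), 1,
              rowSums(atac^2), "+")
  d2 <- pmax(d2, 0)
  best <- apply(d2, 1, which.min)   # which.min = lowest index on ties
  # recompute the winning distance directly so exact matches report 0
  dist_exact <- sqrt(rowSums((atac - rna[best, , drop = FALSE])^2))
  tibble(
    atac_nucleus = rownames(atac),
    rna_nucleus = rownames(rna)[best],
    distance = unname(dist_exact)
  )
}

#' Impute an expression matrix onto ATAC nuclei
#'
#' Copies, for each ATAC nucleus, the expression column of its paired RNA
#' nucleus — no smoothing, so imputation introduces no new values. By
#' default the expression input is depth-normalized log1p
#' ([normalize_log1p()]); pass `normalize = FALSE` for raw pass-through.
#'
#' @param expression Gene x RNA-nucleus matrix.
#' @param pairing Tibble from [pair_nuclei()].
#' @param normalize Depth-normalize and log1p the expression first.
#' @return Dense gene x ATAC-nucleus matrix.
#' @export
impute_expression <- function(expression, pairing, normalize = TRUE) {
  missing <- setdiff(pairing$rna_nucleus, colnames(expression))
  if (length(missing)) {
    abort(paste0("RNA nucleus absent from expression matrix: ", missing[1]))
  }
  mat <- if (normalize) normalize_log1p(expression) else as.matrix(expression)
  out <- mat[, pairing$rna_nucleus, drop = FALSE]
  colnames(out) <- pairing$atac_nucleus
  out
}

#' Cross-modality label agreement of nearest-neighbor matches
#'
#' Samples `n_sample` ATAC nuclei without replacement (seeded), finds each
#' one's nearest RNA nucleus in the shared embedding, and tabulates the
#' (ATAC label, RNA label) pairs. The match rate is the fraction of sampled
#' nuclei whose nearest RNA neighbor carries the same label.
#'
#' @param atac,rna Embedding matrices with nucleus ids as row names.
#' @param labels_atac,labels_rna Named vectors mapping nucleus id to label;
#'   must cover all nuclei of their modality.
#' @param n_sample Number of ATAC nuclei sampled (default 50).
#' @param seed Seed for the sample.
#' @return List with `confusion` (tibble `atac_label`, `rna_label`, `n`),
#'   `match_rate`, and `sampled` (the sampled ATAC ids).
#' @export
knn_match_confusion <- function(atac, rna, labels_atac, labels_rna,
                                n_sample = 50, seed = 1L) {
  if (n_sample > nrow(atac)) {
    abort("n_sample exceeds the number of ATAC nuclei")
  }
  if (!all(rownames(atac) %in% names(labels_atac)) ||
      !all(rownames(rna) %in% names(labels_rna))) {
    abort("labels must cover all nuclei")
  }
  sampled <- withr::with_seed(seed, sample(rownames(atac), n_sample))
  pairing <- pair_nuclei(atac[sampled, , drop = FALSE], rna)
  la <- unname(labels_atac[pairing$atac_nucleus])
  lr <- unname(labels_rna[pairing$rna_nucleus])
  confusion <- tibble(atac_label = la, rna_label = lr) |>
    dplyr::count(.data$atac_label, .data$rna_label, name = "n") |>
    arrange(.data$atac_label, .data$rna_label)
  list(confusion = confusion, match_rate = mean(la == lr), sampled = sampled)
}
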