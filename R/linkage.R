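#' Candidate peak-gene pairs within a symmetric TSS window
#'
#' A peak is a candidate for a gene when the peak midpoint
#' (`floor((start + end) / 2)`) lies in the half-open window
#' `[TSS - half_width, TSS + half_width)`. The default half-width of 250 kb
#' yields the 500 kb symmetric window used for link calling.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `tss`.
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param half_width Window half-width in bp (default 250000).
#' @return Tibble (`gene_id`, `peak_id`, `distance`) where `distance` is the
#'   signed offset peak midpoint minus TSS.
#' @export
candidate_pairs <- function(genes, peaks, half_width = 250000) {
  mid <- floor((peaks$start + peaks$end) / 2)
  peak_gr <- GenomicRanges::GRanges(peaks$chrom,
                                    IRanges::IRanges(mid + 1, mid + 1))
  win_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = genes$tss - half_width + 1,
                     end = genes$tss + half_width)  # [tss-hw, tss+hw) 0-based
  )
  ov <- GenomicRanges::findOverlaps(peak_gr, win_gr)
  pi <- S4Vectors::queryHits(ov)
  gi <- S4Vectors::subjectHits(ov)
  tibble(gene_id = genes$gene_id[gi],
         peak_id = peaks$peak_id[pi],
         distance = mid[pi] - genes$tss[gi]) |>
    arrange(.data$gene_id, .data$distance)
}

#' Pearson correlation links between imputed expression and accessibility
#'
#' For each candidate (gene, peak) pair, computes the sample Pearson
#' correlation across the shared ATAC nuclei between the imputed expression
#' row and the peak accessibility row, with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs involving a constant row are dropped with a message. By default
#' accessibility is depth-normalized log1p before correlating.
#'
#' @param imputed Gene x ATAC-nucleus matrix (see [impute_expression()]).
#' @param atac Peak x ATAC-nucleus count matrix.
#' @param pairs Candidate tibble from [candidate_pairs()].
#' @param normalize_atac Depth-normalize and log1p the accessibility.
#' @return Unfiltered link tibble (`peak_id`, `gene_id`, `distance`, `r`,
#'   `p`).
#' @export
pearson_links <- function(imputed, atac, pairs, normalize_atac = TRUE) {
  shared <- intersect(colnames(imputed), colnames(atac))
  n <- length(shared)
  if (n < 3) abort("need at least 3 shared nuclei to correlate")
  expr <- as.matrix(imputed[, shared, drop = FALSE])
  acc <- if (normalize_atac) {
    normalize_log1p(atac)[, shared, drop = FALSE]
  } else {
    as.matrix(atac[, shared, drop = FALSE])
  }

  gx <- expr[pairs$gene_id, , drop = FALSE]
  px <- acc[pairs$peak_id, , drop = FALSE]
  gs <- gx - rowMeans(gx)
  ps <- px - rowMeans(px)
  gss <- rowSums(gs^2)
  pss <- rowSums(ps^2)
  constant <- gss == 0 | pss == 0
  if (any(constant)) {
    inform(sprintf("dropping %d pair(s) with a constant row", sum(constant)))
  }
  r <- rowSums(gs * ps) / sqrt(gss * pss)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- tibble(peak_id = pairs$peak_id, gene_id = pairs$gene_id,
                distance = pairs$distance, r = unname(r), p = unname(p),
                n = n)
  out[!constant, , drop = FALSE]
}

#' Filter links by correlation and Benjamini-Hochberg FDR
#'
#' Adjusts p-values by Benjamini-Hochberg across all tested pairs (the whole
#' table, not per gene) and accepts links with `r >= r_min` and `q <= q_max`.
#' The correlation cutoff is one-sided (positive links) by default;
#' `signed = TRUE` accepts `|r| >= r_min` instead.
#'
#' @param links Unfiltered link tibble from [pearson_links()].
#' @param r_min Correlation cutoff (default 0.45).
#' @param q_max FDR cutoff (default 1e-4).
#' @param signed Accept strong negative correlations too.
#' @return The link tibble with added `q` and `accepted` columns.
#' @export
filter_links <- function(links, r_min = 0.45, q_max = 1e-4, signed = FALSE) {
  links$q <- bh_adjust(links$p)
  rr <- if (signed) abs(links$r) else links$r
  links$accepted <- rr >= r_min & links$q <= q_max
  links
}

#' Per-gene summary of accepted links
#'
#' Counts linked regions per gene (genes with at least one accepted link)
#' and the mean number of regions per linked gene.
#'
#' @param links Link tibble with an `accepted` column.
#' @return List with `per_gene` (tibble `gene_id`, `n_links`) and
#'   `mean_regions_per_gene`.
#' @export
link_gene_summary <- function(links) {
  acc <- filter(links, .data$accepted)
  if (nrow(acc) == 0) {
    return(list(per_gene = tibble(gene_id = character(), n_links = integer()),
                mean_regions_per_gene = NaN))
  }
  per_gene <- acc |>
    dplyr::count(.data$gene_id, name = "n_links") |>
    arrange(desc(.data$n_links))
  list(per_gene = per_gene,
       mean_regions_per_gene = mean(per_gene$n_links))
}
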