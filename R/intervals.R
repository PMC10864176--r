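# Interval arithmetic and fragment-based scoring. All coordinates follow the
# BED convention: 0-based start (inclusive), end exclusive.

as_granges0 <- function(x, what = "intervals") {
  bad <- which(!(x$start < x$end))
  if (length(bad)) {
    abort(sprintf("malformed interval in %s at record %d (%s:%s-%s)",
                  what, bad[1], x$chrom[bad[1]], x$start[bad[1]],
                  x$end[bad[1]]))
  }
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Merge overlapping and touching genomic intervals
#'
#' Returns the minimal set of non-overlapping intervals covering exactly the
#' same bases. Touching intervals (one's `end` equals the next's `start`)
#' are merged, matching the `reduce` semantics used for peak merging across
#' replicates.
#'
#' @param intervals Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @return Tibble (`chrom`, `start`, `end`, `id`) sorted by position, ids
#'   freshly assigned.
#' @export
#' @examples
#' merge_intervals(tibble::tibble(chrom = "chr1",
#'                                start = c(1, 5), end = c(10, 20)))
merge_intervals <- function(intervals) {
  gr <- as_granges0(intervals)
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
  tibble(chrom = as.character(GenomicRanges::seqnames(red)),
         start = GenomicRanges::start(red) - 1L,
         end = GenomicRanges::end(red),
         id = sprintf("merged_%05d", seq_along(red)))
}

#' Gene-activity scores from Tn5 insertion sites
#'
#' Counts, per gene and nucleus barcode, the Tn5 insertion sites falling in
#' the gene body extended `upstream` bp past the TSS: `[start - upstream,
#' end)` for `+`-strand genes, `[start, end + upstream)` for `-` strand,
#' clamped at zero. Each fragment contributes its two cut sites (`start` and
#' `end - 1`) independently; `mode = "fragment"` instead counts a fragment
#' once if either cut site falls in the window.
#'
#' @param fragments Tibble (`chrom`, `start`, `end`, `barcode`).
#' @param genes Tibble with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @param upstream Upstream extension in bp (default 2000).
#' @param mode Count `"cutsite"`s (default) or whole `"fragment"`s.
#' @return Sparse gene x barcode matrix of counts.
#' @export
gene_activity_scores <- function(fragments, genes, upstream = 2000,
                                 mode = c("cutsite", "fragment")) {
  mode <- match.arg(mode)
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("unknown strand symbol in genes; expected '+' or '-'")
  }
  wstart <- pmax(0, ifelse(genes$strand == "+",
                           genes$start - upstream, genes$start))
  wend <- ifelse(genes$strand == "+", genes$end, genes$end + upstream)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(wstart + 1, wend))

  barcodes <- sort(unique(fragments$barcode))
  pos <- c(fragments$start, fragments$end - 1)
  bc <- rep(match(fragments$barcode, barcodes), 2L)
  frag_ix <- rep(seq_len(nrow(fragments)), 2L)
  cuts <- GenomicRanges::GRanges(rep(fragments$chrom, 2L),
                                 IRanges::IRanges(pos + 1, pos + 1))
  ov <- GenomicRanges::findOverlaps(cuts, win)
  gi <- S4Vectors::subjectHits(ov)
  ci <- S4Vectors::queryHits(ov)
  if (mode == "fragment") {
    key <- paste(frag_ix[ci], gi)
    keep <- !duplicated(key)
    gi <- gi[keep]; ci <- ci[keep]
  }
  m <- sparseMatrix(i = gi, j = bc[ci], x = 1,
                    dims = c(nrow(genes), length(barcodes)),
                    dimnames = list(genes$gene_id, barcodes))
  methods::as(m, "CsparseMatrix")
}

#' Pseudobulk log2(CPM) aggregation
#'
#' Sums counts over the nuclei of each group, scales each group to counts
#' per million, and returns `log2(CPM + pseudocount)`. A second level of
#' aggregation (e.g. donors within a stage) is a plain mean of the log
#' values, provided by [average_log_groups()].
#'
#' @param counts Feature x nucleus matrix.
#' @param groups Named character vector mapping every nucleus (column) to a
#'   group, or a tibble with columns `nucleus` and `group`.
#' @param pseudocount Added inside the log (default 1; plain log2(CPM) is
#'   undefined at zero counts).
#' @return Dense feature x group matrix of log2(CPM + pseudocount).
#' @export
pseudobulk_log2cpm <- function(counts, groups, pseudocount = 1) {
  if (is.data.frame(groups)) {
    groups <- setNames(groups$group, groups$nucleus)
  }
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    abort(paste0("nuclei without group assignment: ", missing[1], " ..."))
  }
  g <- factor(groups[colnames(counts)])
  agg <- vapply(levels(g), function(lv) {
    Matrix::rowSums(counts[, g == lv, drop = FALSE])
  }, numeric(nrow(counts)))
  totals <- colSums(agg)
  if (any(totals == 0)) {
    abort(paste0("group with zero total counts: ",
                 levels(g)[which(totals == 0)[1]]))
  }
  cpm <- sweep(agg, 2, 1e6 / totals, "*")
  out <- log2(cpm + pseudocount)
  rownames(out) <- rownames(counts)
  out
}

#' @rdname pseudobulk_log2cpm
#' @param log_mat Feature x group matrix of log values.
#' @param mapping Named character vector mapping each column of `log_mat` to
#'   a higher-level group.
#' @export
average_log_groups <- function(log_mat, mapping) {
  g <- factor(mapping[colnames(log_mat)])
  out <- vapply(levels(g), function(lv) {
    rowMeans(log_mat[, g == lv, drop = FALSE])
  }, numeric(nrow(log_mat)))
  rownames(out) <- rownames(log_mat)
  out
}

#' Overlap percentage between two peak sets
#'
#' Fraction of query intervals having at least `min_overlap` bases of
#' intersection with any reference interval — the summary statistic used to
#' validate predicted enhancers against an external peak set (e.g. CUT&Tag).
#'
#' @param query,reference Interval tibbles (`chrom`, `start`, `end`, and
#'   optionally `id`).
#' @param min_overlap Minimum intersection width in bp (default 1).
#' @return List with `fraction` (scalar) and `flags`, a tibble with one row
#'   per query interval and a logical `overlaps` column.
#' @export
overlap_percentage <- function(query, reference, min_overlap = 1) {
  if (nrow(query) == 0) abort("empty query: overlap fraction is undefined")
  q <- as_granges0(query, "query")
  r <- as_granges0(reference, "reference")
  # disjoint chromosome sets are a legitimate zero-overlap case, not a
  # seqlevel mismatch worth warning about
  ov <- suppressWarnings(
    GenomicRanges::countOverlaps(q, r, minoverlap = min_overlap) > 0
  )
  flags <- tibble(
    id = if ("id" %in% names(query)) query$id else
      sprintf("q_%05d", seq_len(nrow(query))),
    chrom = query$chrom, start = query$start, end = query$end,
    overlaps = as.logical(ov)
  )
  list(fraction = mean(ov), flags = flags)
}
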