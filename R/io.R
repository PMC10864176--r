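#' Read and write sparse count matrices in Matrix Market layout
#'
#' A count directory holds `matrix.mtx` (1-based indices on disk), a
#' `features.tsv` and a `barcodes.tsv`, the layout emitted by the common
#' single-cell pipelines. In memory, matrices are feature x nucleus sparse
#' `Matrix` objects with dimnames.
#'
#' @param counts Feature x nucleus matrix with dimnames.
#' @param dir Directory holding (or to hold) the three files.
#' @return `write_counts()` returns `dir` invisibly; `read_counts()` the
#'   sparse matrix.
#' @export
write_counts <- function(counts, dir) {
  check_named_matrix(counts, "counts")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix(counts, sparse = TRUE), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_lines(rownames(counts), file.path(dir, "features.tsv"))
  readr::write_lines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts
#' @export
read_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  m <- methods::as(m, "CsparseMatrix")
  rownames(m) <- readr::read_lines(file.path(dir, "features.tsv"))
  colnames(m) <- readr::read_lines(file.path(dir, "barcodes.tsv"))
  m
}

#' Read and write BED intervals as tibbles
#'
#' On disk BED is 0-based half-open; in memory the same convention is kept
#' (`start` 0-based inclusive, `end` exclusive), so values round-trip
#' unchanged. Parsing and serialization are delegated to rtracklayer.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional `id`, `strand`.
#' @param path File path.
#' @return `read_bed()` returns a tibble (`chrom`, `start`, `end`, `id`,
#'   `strand`); `write_bed()` returns `path` invisibly.
#' @export
write_bed <- function(x, path) {
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    abort(paste0("malformed interval at record ", bad, ": start >= end"))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = if ("strand" %in% names(x)) x$strand else "*"
  )
  if ("id" %in% names(x)) names(gr) <- x$id
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  nm <- gr$name
  out$id <- if (is.null(nm)) sprintf("iv_%05d", seq_len(nrow(out))) else nm
  select(out, "chrom", "start", "end", "id", "strand")
}

#' Read and write dense numeric matrices as TSV
#'
#' First column `id` holds row names; remaining columns are numeric.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return `read_tsv_matrix()` returns the matrix; `write_tsv_matrix()`
#'   returns `path` invisibly.
#' @export
write_tsv_matrix <- function(m, path) {
  check_named_matrix(m, "matrix")
  df <- bind_cols(tibble(id = rownames(m)), as_tibble(as.matrix(m)))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
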