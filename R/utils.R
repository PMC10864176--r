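# Internal helpers shared across modules.

# Derive a deterministic sub-stream seed (< 2^31) from a root seed and a
# stage offset, so stages can be re-run independently yet reproducibly.
substream_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 59999L) * 31013 + as.numeric(offset) * 7919 + 17
  as.integer(s %% 2147483647)
}

# Run code under a derived seed without disturbing the caller's RNG state.
with_substream <- function(seed, offset, code) {
  withr::with_seed(substream_seed(seed, offset), code)
}

# softplus, numerically stable for large |x|
softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

#' Depth-normalize and log-transform a count matrix
#'
#' Scales each column (nucleus) to a common total (`scale_to`), then applies
#' `log1p`. This is the standard normalization applied to expression and
#' accessibility values before correlation or rank testing.
#'
#' @param counts A feature x nucleus matrix (dense or `Matrix` sparse).
#' @param scale_to Target column total after depth scaling (default `1e4`).
#' @return A matrix of the same shape with normalized log1p values.
#' @export
normalize_log1p <- function(counts, scale_to = 1e4) {
  cs <- Matrix::colSums(counts)
  cs[cs == 0] <- 1
  out <- counts %*% Matrix::Diagonal(x = scale_to / cs)
  colnames(out) <- colnames(counts)
  log1p(as.matrix(out))
}

# Validate a feature x nucleus matrix with dimnames
check_named_matrix <- function(m, what = "matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(paste0(what, " must carry row and column names"))
  }
  invisible(m)
}

# Benjamini-Hochberg wrapper kept in one place so every module adjusts the
# same way.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
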