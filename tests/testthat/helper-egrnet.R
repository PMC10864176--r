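# Shared fixtures, built in code. Small datasets are cached per session so
# several test files can reuse them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

small_config <- function(seed = 3, ...) {
  sim_config(n_rna_nuclei = 80, n_atac_nuclei = 80, n_genes = 60,
             n_peaks = 200, n_tf_programs = 3, targets_per_tf = 3,
             decoy_motifs = 15, seed = seed, ...)
}

small_multiome <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_multiome(small_config())
  }
  .fixture_cache$small
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 10000,
                             max_width = 300) {
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = sample.int(span, n, replace = TRUE) - 1L
  ) |>
    dplyr::mutate(end = start + sample.int(max_width, n, replace = TRUE),
                  id = sprintf("iv_%04d", seq_len(n)))
}

# Brute-force per-base coverage mask of an interval set, one chromosome.
coverage_mask <- function(iv, len) {
  mask <- logical(len)
  for (i in seq_len(nrow(iv))) {
    mask[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  mask
}
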