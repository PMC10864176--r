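#' Simulate paired RNA/ATAC counts from latent coordinates and programs
#'
#' RNA counts are negative-binomial (or Poisson with `poisson_rna = TRUE`)
#' with per-gene mean `softplus(intercept + loadings . latent)`, modulated
#' multiplicatively by the planted programs and scaled so each nucleus's
#' expected depth is `rna_depth_mean`. ATAC counts are Poisson: decoy peaks
#' have a flat rate (independent of every TF's expression by construction)
#' while enhancer peaks are multiplied by `exp(effect_size)` in their
#' program's cluster, scaled to `atac_depth_mean` per nucleus.
#'
#' @param latent Output of [simulate_trajectory_latent()].
#' @param programs Output of [plant_regulatory_program()].
#' @param config The shared [sim_config()].
#' @return A `paired_multiome` list: sparse `rna` (gene x nucleus) and
#'   `atac` (peak x nucleus) count matrices, `latent` embeddings, `truth`,
#'   the genomic tables from `programs`, and `config`.
#' @export
simulate_counts <- function(latent, programs, config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- latent$truth
  rna_truth <- filter(truth, .data$modality == "rna")
  atac_truth <- filter(truth, .data$modality == "atac")

  prog_tbl <- distinct(programs$programs, .data$tf_gene, .data$cluster)
  target_tbl <- distinct(programs$programs, .data$target_gene, .data$cluster)
  enh_tbl <- distinct(programs$programs, .data$enhancer_peak, .data$cluster)

  with_substream(config$seed, 301L, {
    n_g <- config$n_genes
    n_rna <- config$n_rna_nuclei
    loadings <- matrix(rnorm(n_g * config$latent_dim, sd = 0.3),
                       n_g, config$latent_dim)
    # program genes are driven by their TF program alone: their baseline
    # does not ride the trajectory, so the planted coupling is the signal
    program_gene <- programs$genes$role != "background"
    loadings[program_gene, ] <- 0
    intercept <- rnorm(n_g, mean = 0.5, sd = 0.8)
    mu <- softplus(sweep(loadings %*% Matrix::t(latent$latent$rna), 1,
                         intercept, "+"))
    mu <- as.matrix(mu)
    rownames(mu) <- programs$genes$gene_id
    colnames(mu) <- rna_truth$nucleus

    # program modulation: TF and target genes up in the program's cluster
    bump <- exp(config$effect_size)
    for (i in seq_len(nrow(prog_tbl))) {
      in_cl <- rna_truth$true_cluster == prog_tbl$cluster[i]
      mu[prog_tbl$tf_gene[i], in_cl] <- mu[prog_tbl$tf_gene[i], in_cl] * bump
    }
    for (i in seq_len(nrow(target_tbl))) {
      in_cl <- rna_truth$true_cluster == target_tbl$cluster[i]
      mu[target_tbl$target_gene[i], in_cl] <-
        mu[target_tbl$target_gene[i], in_cl] * bump
    }
    if (any(!is.finite(mu))) abort("non-finite RNA means")
    mu <- sweep(mu, 2, config$rna_depth_mean / colSums(mu), "*")

    rna_counts <- if (config$poisson_rna) {
      matrix(rpois(length(mu), lambda = mu), nrow(mu), ncol(mu))
    } else {
      matrix(rnbinom(length(mu), mu = mu, size = config$nb_dispersion),
             nrow(mu), ncol(mu))
    }
    dimnames(rna_counts) <- dimnames(mu)

    # ATAC: flat decoys, program-modulated enhancers
    n_p <- config$n_peaks
    lam <- matrix(1, n_p, config$n_atac_nuclei,
                  dimnames = list(programs$peaks$peak_id, atac_truth$nucleus))
    for (i in seq_len(nrow(enh_tbl))) {
      in_cl <- atac_truth$true_cluster == enh_tbl$cluster[i]
      lam[enh_tbl$enhancer_peak[i], in_cl] <-
        lam[enh_tbl$enhancer_peak[i], in_cl] * bump
    }
    if (any(!is.finite(lam))) abort("non-finite ATAC rates")
    lam <- sweep(lam, 2, config$atac_depth_mean / colSums(lam), "*")
    atac_counts <- matrix(rpois(length(lam), lambda = lam),
                          nrow(lam), ncol(lam))
    dimnames(atac_counts) <- dimnames(lam)

    structure(
      list(rna = methods::as(Matrix(rna_counts, sparse = TRUE), "CsparseMatrix"),
           atac = methods::as(Matrix(atac_counts, sparse = TRUE), "CsparseMatrix"),
           latent = latent$latent,
           truth = truth,
           paths = latent$paths,
           genes = programs$genes,
           peaks = programs$peaks,
           motif_hits = programs$motif_hits,
           motif_truth = programs$motif_truth,
           programs = programs$programs,
           planted_links = programs$planted_links,
           config = config),
      class = "paired_multiome"
    )
  })
}

#' Simulate a complete paired multiome dataset
#'
#' Convenience wrapper chaining [simulate_trajectory_latent()],
#' [plant_regulatory_program()] and [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return A `paired_multiome` object; see [simulate_counts()].
#' @export
#' @examples
#' ds <- simulate_multiome(sim_config(n_rna_nuclei = 60, n_atac_nuclei = 60,
#'                                    n_genes = 40, n_peaks = 120,
#'                                    targets_per_tf = 2, seed = 7))
#' dim(ds$rna)
simulate_multiome <- function(config) {
  latent <- simulate_trajectory_latent(config)
  programs <- plant_regulatory_program(config)
  simulate_counts(latent, programs, config)
}

#' @export
print.paired_multiome <- function(x, ...) {
  cat("<paired_multiome>\n")
  cat(sprintf("  rna: %d genes x %d nuclei; atac: %d peaks x %d nuclei\n",
              nrow(x$rna), ncol(x$rna), nrow(x$atac), ncol(x$atac)))
  cat(sprintf("  planted links: %d; motifs: %d (%d decoy)\n",
              nrow(x$planted_links), nrow(x$motif_truth),
              x$config$decoy_motifs))
  invisible(x)
}

#' Draw fragment records consistent with simulated ATAC counts
#'
#' For every nonzero peak count, draws that many fragments uniformly inside
#' the peak interval for the corresponding nucleus barcode. Intended for
#' exercising fragment-based operations (gene-activity scoring) at small
#' scale; fragment totals grow with `atac_depth_mean`, so use a small
#' configuration.
#'
#' @param dataset A `paired_multiome`.
#' @param max_fragments Safety cap on the number of fragments drawn.
#' @return Tibble (`chrom`, `start`, `end`, `barcode`), 0-based half-open.
#' @export
simulate_fragments <- function(dataset, max_fragments = 2e6) {
  stopifnot(inherits(dataset, "paired_multiome"))
  m <- methods::as(dataset$atac, "TsparseMatrix")
  total <- sum(m@x)
  if (total > max_fragments) {
    abort("fragment total exceeds max_fragments; use a smaller config")
  }
  with_substream(dataset$config$seed, 401L, {
    peak_row <- match(rownames(m)[m@i + 1L], dataset$peaks$peak_id)
    reps <- as.integer(m@x)
    idx <- rep(seq_along(reps), reps)
    p <- peak_row[idx]
    width <- dataset$peaks$end[p] - dataset$peaks$start[p]
    frag_len <- pmin(pmax(floor(rnorm(length(p), 150, 30)), 30), width)
    s <- dataset$peaks$start[p] +
      floor(runif(length(p)) * (width - frag_len + 1))
    tibble(chrom = dataset$peaks$chrom[p],
           start = s, end = s + frag_len,
           barcode = colnames(m)[m@j + 1L][idx]) |>
      arrange(.data$chrom, .data$start, .data$end, .data$barcode)
  })
}
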