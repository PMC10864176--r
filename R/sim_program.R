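#' Plant TF -> enhancer -> target-gene programs on a synthetic chromosome
#'
#' Places genes and peaks on one synthetic chromosome (0-based half-open
#' coordinates) and wires up the planted regulatory programs: each TF program
#' owns `targets_per_tf` target genes, each target gets
#' `enhancers_per_target` enhancer peaks whose midpoints fall within
#' `window_half_width` of the target's TSS, and every enhancer carries a
#' high-scoring hit of its TF's motif. Decoy peaks are placed both inside and
#' outside gene windows (`decoy_inside_frac`) and carry no program. Decoy
#' motifs hit random peaks. Gene windows are laid out non-overlapping so a
#' peak is a candidate for at most one gene.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles `genes` (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `role`), `peaks` (`peak_id`, `chrom`, `start`, `end`,
#'   `type`), `motif_hits` (`peak_id`, `motif_id`, `score`), `motif_truth`
#'   (`motif_id`, `tf_gene`), `programs` (`tf_gene`, `enhancer_peak`,
#'   `target_gene`, `cluster`) and `planted_links` (`peak_id`, `gene_id`).
#' @export
plant_regulatory_program <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hw <- config$window_half_width
  pw <- config$peak_width
  gene_region <- 0.6 * config$chrom_length
  spacing <- floor(gene_region / config$n_genes)
  if (spacing < max(2 * hw, 4 * pw, 1000)) {
    abort("chrom_length too short to place non-overlapping gene windows")
  }
  if (0.3 * config$chrom_length < 2 * hw + 10 * pw) {
    abort("chrom_length leaves no gene-free region for outside decoys")
  }

  with_substream(config$seed, 201L, {
    n_genes <- config$n_genes
    gene_len <- floor(runif(n_genes, 5000, 20000))
    tss <- as.numeric((seq_len(n_genes) - 1L)) * spacing + hw +
      floor(runif(n_genes, 0, spacing / 8))
    strand <- rep(c("+", "-"), length.out = n_genes)
    start <- ifelse(strand == "+", tss, tss - gene_len + 1)
    end <- ifelse(strand == "+", tss + gene_len, tss + 1)
    genes <- tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_genes)),
      chrom = "chrS", start = start, end = end,
      strand = strand, tss = tss
    )

    # program gene roles
    n_prog_genes <- config$n_tf_programs * (1 + config$targets_per_tf)
    prog_idx <- sort(sample(n_genes, n_prog_genes))
    tf_idx <- prog_idx[seq_len(config$n_tf_programs)]
    target_idx <- setdiff(prog_idx, tf_idx)
    genes$role <- "background"
    genes$role[tf_idx] <- "tf"
    genes$role[target_idx] <- "target"

    clusters <- sprintf("c%d", ((seq_len(config$n_tf_programs) - 1L) %%
                                  config$n_clusters) + 1L)
    tf_gene <- genes$gene_id[tf_idx]
    target_split <- split(genes$gene_id[match(target_idx, seq_len(n_genes))],
                          rep(seq_len(config$n_tf_programs),
                              each = config$targets_per_tf))

    # enhancer placement: midpoint within the target's window
    placed_start <- numeric(0)
    placed_end <- numeric(0)
    place_peak <- function(lo, hi) {
      for (i in seq_len(200)) {
        mid <- floor(runif(1, lo, hi))
        s <- mid - floor(pw / 2)
        e <- s + pw
        if (s < 0 || e > config$chrom_length) next
        if (!any(s < placed_end & e > placed_start)) {
          placed_start <<- c(placed_start, s)
          placed_end <<- c(placed_end, e)
          return(c(s, e))
        }
      }
      abort("peak placement failed after bounded retries")
    }

    prog_rows <- list()
    enh_start <- numeric(0); enh_end <- numeric(0)
    enh_tf <- character(0); enh_target <- character(0); enh_cluster <- character(0)
    for (p in seq_len(config$n_tf_programs)) {
      for (g in target_split[[p]]) {
        g_tss <- genes$tss[genes$gene_id == g]
        for (k in seq_len(config$enhancers_per_target)) {
          se <- place_peak(g_tss - hw + pw, g_tss + hw - pw)
          enh_start <- c(enh_start, se[1]); enh_end <- c(enh_end, se[2])
          enh_tf <- c(enh_tf, tf_gene[p])
          enh_target <- c(enh_target, g)
          enh_cluster <- c(enh_cluster, clusters[p])
        }
      }
    }

    # decoys: inside a random gene window or in the gene-free tail
    n_decoy <- config$n_peaks - length(enh_start)
    inside <- runif(n_decoy) < config$decoy_inside_frac
    dec_start <- numeric(n_decoy); dec_end <- numeric(n_decoy)
    tail_lo <- 0.7 * config$chrom_length + hw
    tail_hi <- config$chrom_length - pw
    for (i in seq_len(n_decoy)) {
      se <- if (inside[i]) {
        g_tss <- genes$tss[sample(n_genes, 1)]
        place_peak(g_tss - hw + pw, g_tss + hw - pw)
      } else {
        place_peak(tail_lo, tail_hi)
      }
      dec_start[i] <- se[1]; dec_end[i] <- se[2]
    }

    peaks <- tibble(
      chrom = "chrS",
      start = c(enh_start, dec_start),
      end = c(enh_end, dec_end),
      type = c(rep("enhancer", length(enh_start)),
               ifelse(inside, "decoy_inside", "decoy_outside"))
    ) |> arrange(.data$start)
    peaks$peak_id <- sprintf("peak_%04d", seq_len(nrow(peaks)))
    peaks <- select(peaks, "peak_id", "chrom", "start", "end", "type")

    # map enhancer coordinates back to their sorted ids
    enh_key <- paste(enh_start, enh_end)
    peak_key <- paste(peaks$start, peaks$end)
    enh_ids <- peaks$peak_id[match(enh_key, peak_key)]

    programs <- tibble(tf_gene = enh_tf, enhancer_peak = enh_ids,
                       target_gene = enh_target, cluster = enh_cluster)

    # motifs: one true motif per TF, plus decoy motifs mapped to distinct
    # background genes
    true_motifs <- sprintf("motif_%s", tf_gene)
    bg_genes <- genes$gene_id[genes$role == "background"]
    if (length(bg_genes) < config$decoy_motifs) {
      abort("not enough background genes to assign decoy motifs")
    }
    decoy_motif_gene <- sample(bg_genes, config$decoy_motifs)
    decoy_motifs <- sprintf("motif_D%03d", seq_len(config$decoy_motifs))
    motif_truth <- tibble(
      motif_id = c(true_motifs, decoy_motifs),
      tf_gene = c(tf_gene, decoy_motif_gene)
    )

    hit_rows <- list()
    for (p in seq_len(config$n_tf_programs)) {
      own <- programs$enhancer_peak[programs$tf_gene == tf_gene[p]]
      bg_n <- max(1L, floor(0.02 * nrow(peaks)))
      bg <- sample(setdiff(peaks$peak_id, own), bg_n)
      hit_rows[[length(hit_rows) + 1L]] <- tibble(
        peak_id = c(own, bg),
        motif_id = true_motifs[p],
        score = c(runif(length(own), 8, 12), runif(length(bg), 0.5, 4))
      )
    }
    for (d in seq_len(config$decoy_motifs)) {
      n_hit <- max(2L, floor(0.05 * nrow(peaks)))
      hp <- sample(peaks$peak_id, n_hit)
      hit_rows[[length(hit_rows) + 1L]] <- tibble(
        peak_id = hp, motif_id = decoy_motifs[d],
        score = runif(n_hit, 0.5, 6)
      )
    }
    motif_hits <- bind_rows(hit_rows)

    list(
      genes = genes,
      peaks = peaks,
      motif_hits = motif_hits,
      motif_truth = motif_truth,
      programs = programs,
      planted_links = distinct(tibble(peak_id = programs$enhancer_peak,
                                      gene_id = programs$target_gene))
    )
  })
}
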