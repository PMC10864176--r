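#' Configuration for the synthetic paired-multiome generator
#'
#' Bundles every knob of the generator: cohort sizes, feature counts, the
#' planted regulatory programs, the latent bifurcating trajectory, count
#' depths and noise levels, and genomic placement. Identical configurations
#' (including `seed`) produce identical datasets, down to the bytes of any
#' files written.
#'
#' The defaults describe the reference simulation used throughout the
#' package's validation suite: 400 nuclei per modality, 300 genes, 1,200
#' peaks on one synthetic chromosome, three planted TF programs with ten
#' target genes each and one enhancer per target, a bifurcating trajectory
#' (root plus two branches) with moderate latent noise, negative-binomial
#' RNA counts and Poisson ATAC counts.
#'
#' @param n_rna_nuclei,n_atac_nuclei Nuclei per modality.
#' @param n_genes,n_peaks Feature counts (peaks include planted enhancers).
#' @param n_tf_programs Number of planted TF -> enhancer -> target programs.
#' @param targets_per_tf Target genes per TF program.
#' @param enhancers_per_target Enhancer peaks planted per target gene.
#' @param n_clusters Number of nucleus clusters along the trajectory; must be
#'   >= 3 when `bifurcate = TRUE` (root, branch A, branch B).
#' @param bifurcate If `TRUE` the latent trajectory is root -> (branch A,
#'   branch B); otherwise a single linear path.
#' @param latent_dim Dimension of the shared latent space (>= 2).
#' @param noise_sd Isotropic latent noise standard deviation (>= 0).
#' @param rna_depth_mean,atac_depth_mean Expected counts per nucleus.
#' @param nb_dispersion Negative-binomial size parameter for RNA counts; set
#'   `poisson_rna = TRUE` for the Poisson limit.
#' @param poisson_rna Draw RNA counts as Poisson instead of NB.
#' @param effect_size Program coupling strength on the log-rate scale: TF
#'   expression, enhancer accessibility and target expression are multiplied
#'   by `exp(effect_size)` in the program's cluster. `0` disables all
#'   programs (null data).
#' @param chrom_length Length (bp) of the single synthetic chromosome.
#' @param window_half_width Half-width (bp) of the gene linkage window; the
#'   default 250 kb gives the 500 kb symmetric window used for link calling.
#' @param peak_width Width (bp) of every simulated peak.
#' @param decoy_motifs Number of decoy motifs with random peak hits.
#' @param decoy_inside_frac Fraction of decoy (non-enhancer) peaks placed
#'   inside some gene's linkage window; the rest are placed in a gene-free
#'   region of the chromosome.
#' @param seed Root seed; every sub-stream derives from it.
#' @return A `sim_config` list with validated fields.
#' @export
#' @examples
#' cfg <- sim_config(n_rna_nuclei = 50, n_atac_nuclei = 50, seed = 1)
sim_config <- function(n_rna_nuclei = 400,
                       n_atac_nuclei = 400,
                       n_genes = 300,
                       n_peaks = 1200,
                       n_tf_programs = 3,
                       targets_per_tf = 10,
                       enhancers_per_target = 1,
                       n_clusters = 3,
                       bifurcate = TRUE,
                       latent_dim = 10,
                       noise_sd = 0.1,
                       rna_depth_mean = 5000,
                       atac_depth_mean = 4000,
                       nb_dispersion = 2,
                       poisson_rna = FALSE,
                       effect_size = 2,
                       chrom_length = 4e8,
                       window_half_width = 250000,
                       peak_width = 500,
                       decoy_motifs = 50,
                       decoy_inside_frac = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_rna_nuclei = as.integer(n_rna_nuclei),
    n_atac_nuclei = as.integer(n_atac_nuclei),
    n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks),
    n_tf_programs = as.integer(n_tf_programs),
    targets_per_tf = as.integer(targets_per_tf),
    enhancers_per_target = as.integer(enhancers_per_target),
    n_clusters = as.integer(n_clusters),
    bifurcate = isTRUE(bifurcate),
    latent_dim = as.integer(latent_dim),
    noise_sd = as.numeric(noise_sd),
    rna_depth_mean = as.numeric(rna_depth_mean),
    atac_depth_mean = as.numeric(atac_depth_mean),
    nb_dispersion = as.numeric(nb_dispersion),
    poisson_rna = isTRUE(poisson_rna),
    effect_size = as.numeric(effect_size),
    chrom_length = as.numeric(chrom_length),
    window_half_width = as.numeric(window_half_width),
    peak_width = as.numeric(peak_width),
    decoy_motifs = as.integer(decoy_motifs),
    decoy_inside_frac = as.numeric(decoy_inside_frac),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_rna_nuclei", "n_atac_nuclei", "n_genes", "n_peaks",
              "n_tf_programs", "targets_per_tf", "enhancers_per_target",
              "n_clusters", "latent_dim", "decoy_motifs")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) {
      abort(paste0("sim_config field '", f, "' must be a count >= 1"))
    }
  }
  if (cfg$latent_dim < 2) abort("latent_dim must be >= 2")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0")
  if (cfg$window_half_width <= 0) abort("window_half_width must be > 0")
  if (cfg$nb_dispersion <= 0) abort("nb_dispersion must be > 0")
  if (cfg$decoy_inside_frac < 0 || cfg$decoy_inside_frac > 1) {
    abort("decoy_inside_frac must be in [0, 1]")
  }
  n_planted <- cfg$n_tf_programs * cfg$targets_per_tf * cfg$enhancers_per_target
  if (n_planted >= cfg$n_peaks) {
    abort("n_peaks must exceed the number of planted enhancer peaks")
  }
  n_program_genes <- cfg$n_tf_programs * (1 + cfg$targets_per_tf)
  if (n_program_genes > cfg$n_genes) {
    abort("n_genes too small for the requested TF programs")
  }
  if (cfg$bifurcate && cfg$n_clusters < 3) {
    abort("a bifurcating trajectory needs n_clusters >= 3")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  nuclei: %d RNA / %d ATAC; %d genes, %d peaks\n",
              x$n_rna_nuclei, x$n_atac_nuclei, x$n_genes, x$n_peaks))
  cat(sprintf("  programs: %d TFs x %d targets x %d enhancers; effect %.2f\n",
              x$n_tf_programs, x$targets_per_tf, x$enhancers_per_target,
              x$effect_size))
  cat(sprintf("  trajectory: %s, latent dim %d, noise sd %.3f; seed %d\n",
              if (x$bifurcate) "bifurcating" else "linear",
              x$latent_dim, x$noise_sd, x$seed))
  invisible(x)
}
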