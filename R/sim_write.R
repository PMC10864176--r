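#' Write a simulated paired multiome dataset to disk
#'
#' Emits the on-disk fixture layout consumed by the pipeline readers:
#' Matrix Market counts with feature/barcode lists per modality
#' (`rna/`, `atac/`), `peaks.bed` (0-based half-open, BED3+name),
#' `genes.tsv`, `motif_hits.tsv`, label and latent TSVs, the ground-truth
#' tables (`truth_*.tsv`) and a `manifest.yaml` recording the full
#' configuration including the seed. Writing the same dataset twice produces
#' byte-identical files.
#'
#' @param dataset A `paired_multiome` from [simulate_multiome()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param fragments If `TRUE`, also draw and write `fragments.tsv` via
#'   [simulate_fragments()] (only sensible for small configurations).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(dataset, dir, overwrite = FALSE, fragments = FALSE) {
  stopifnot(inherits(dataset, "paired_multiome"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    abort(paste0("directory ", dir, " is non-empty; pass overwrite = TRUE"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  write_counts(dataset$rna, file.path(dir, "rna"))
  write_counts(dataset$atac, file.path(dir, "atac"))
  write_bed(rename(dataset$peaks, id = "peak_id"), file.path(dir, "peaks.bed"))
  readr::write_tsv(dataset$genes, file.path(dir, "genes.tsv"))
  readr::write_tsv(dataset$motif_hits, file.path(dir, "motif_hits.tsv"))
  readr::write_tsv(dataset$motif_truth, file.path(dir, "truth_motifs.tsv"))
  readr::write_tsv(dataset$truth, file.path(dir, "labels.tsv"))
  write_tsv_matrix(dataset$latent$rna, file.path(dir, "latent_rna.tsv"))
  write_tsv_matrix(dataset$latent$atac, file.path(dir, "latent_atac.tsv"))
  readr::write_tsv(dataset$programs, file.path(dir, "truth_programs.tsv"))
  readr::write_tsv(dataset$planted_links, file.path(dir, "truth_links.tsv"))
  paths_tbl <- bind_rows(lapply(names(dataset$paths), function(nm) {
    wp <- dataset$paths[[nm]]
    tibble(path = nm, order = seq_len(nrow(wp)), x = wp[, 1], y = wp[, 2])
  }))
  readr::write_tsv(paths_tbl, file.path(dir, "truth_paths.tsv"))
  if (fragments) {
    readr::write_tsv(simulate_fragments(dataset),
                     file.path(dir, "fragments.tsv"))
  }
  yaml::write_yaml(unclass(dataset$config), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a fixture directory back into a `paired_multiome`
#'
#' Inverse of [write_fixture()]; counts round-trip exactly.
#'
#' @param dir Directory written by [write_fixture()].
#' @return A `paired_multiome` object.
#' @export
read_fixture <- function(dir) {
  if (!file.exists(file.path(dir, "manifest.yaml"))) {
    abort(paste0("no manifest.yaml under ", dir))
  }
  cfg <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  peaks <- read_bed(file.path(dir, "peaks.bed")) |>
    rename(peak_id = "id") |>
    select("peak_id", "chrom", "start", "end")
  paths_tbl <- readr::read_tsv(file.path(dir, "truth_paths.tsv"),
                               show_col_types = FALSE)
  paths <- lapply(split(paths_tbl, paths_tbl$path), function(d) {
    d <- d[order(d$order), ]
    unname(cbind(d$x, d$y))
  })
  structure(
    list(rna = read_counts(file.path(dir, "rna")),
         atac = read_counts(file.path(dir, "atac")),
         latent = list(rna = read_tsv_matrix(file.path(dir, "latent_rna.tsv")),
                       atac = read_tsv_matrix(file.path(dir, "latent_atac.tsv"))),
         truth = readr::read_tsv(file.path(dir, "labels.tsv"),
                                 show_col_types = FALSE),
         paths = paths,
         genes = readr::read_tsv(file.path(dir, "genes.tsv"),
                                 show_col_types = FALSE),
         peaks = peaks,
         motif_hits = readr::read_tsv(file.path(dir, "motif_hits.tsv"),
                                      show_col_types = FALSE),
         motif_truth = readr::read_tsv(file.path(dir, "truth_motifs.tsv"),
                                       show_col_types = FALSE),
         programs = readr::read_tsv(file.path(dir, "truth_programs.tsv"),
                                    show_col_types = FALSE),
         planted_links = readr::read_tsv(file.path(dir, "truth_links.tsv"),
                                         show_col_types = FALSE),
         config = config),
    class = "paired_multiome"
  )
}
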