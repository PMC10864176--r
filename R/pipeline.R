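#' Pipeline configuration with study-default thresholds
#'
#' Bundles every threshold of the end-to-end workflow, pre-filled with the
#' defaults used throughout the package: 250 kb window half-width (500 kb
#' symmetric window), link acceptance at r >= 0.45 and BH FDR <= 1e-4,
#' marker filters min.pct = 0.1 / log2FC >= 0.25, DAR filters p < 0.001 /
#' log2FC >= 1 / top 5000, motif-enrichment AUC fraction 0.001 with a
#' 20-rank floor, NES floor 3.0, and 5 regulators per cluster. The
#' configuration round-trips through YAML unchanged.
#'
#' @param sim A [sim_config()] describing the dataset to simulate (or the
#'   manifest of a fixture to load).
#' @param fixture_dir Optional directory: load a written fixture instead of
#'   simulating.
#' @param window_half_width,r_min,q_max Linkage thresholds.
#' @param min_pct,logfc_min Marker thresholds.
#' @param dar_p_max,dar_log2fc_min,dar_top_k DAR thresholds.
#' @param auc_fraction,min_top,nes_floor,per_cluster_top TF-mining knobs.
#' @param out_dir Optional output directory for links/network files.
#' @param verbose Emit stage messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            fixture_dir = NULL,
                            window_half_width = 250000,
                            r_min = 0.45,
                            q_max = 1e-4,
                            min_pct = 0.1,
                            logfc_min = 0.25,
                            dar_p_max = 0.001,
                            dar_log2fc_min = 1,
                            dar_top_k = 5000,
                            auc_fraction = 0.001,
                            min_top = 20,
                            nes_floor = 3,
                            per_cluster_top = 5,
                            out_dir = NULL,
                            verbose = FALSE) {
  structure(list(sim = sim, fixture_dir = fixture_dir,
                 window_half_width = window_half_width, r_min = r_min,
                 q_max = q_max, min_pct = min_pct, logfc_min = logfc_min,
                 dar_p_max = dar_p_max, dar_log2fc_min = dar_log2fc_min,
                 dar_top_k = dar_top_k, auc_fraction = auc_fraction,
                 min_top = min_top, nes_floor = nes_floor,
                 per_cluster_top = per_cluster_top, out_dir = out_dir,
                 verbose = verbose),
            class = "pipeline_config")
}

#' Fit root and branch paths from cluster labels on a 2-D embedding
#'
#' Supervised path construction for a bifurcating population: the root
#' cluster's principal axis (oriented toward the branches) spans the root
#' path; each branch extends from the root's far end along the direction of
#' its clusters' median, out to the farthest projected nucleus.
#'
#' @param embedding Nucleus x 2 matrix with row names.
#' @param labels Named vector mapping nucleus to cluster.
#' @param root_label Cluster label of the shared progenitor population.
#' @param branch_labels Named list: branch name -> character vector of that
#'   branch's cluster labels, ordered root-outward.
#' @return List with `root` (a `trajectory_path`) and `branches` (named
#'   list of `trajectory_path`s starting at the root terminus).
#' @export
fit_branching_paths <- function(embedding, labels, root_label,
                                branch_labels) {
  labels <- labels[rownames(embedding)]
  pts <- as.matrix(embedding[, 1:2, drop = FALSE])
  root_pts <- pts[which(labels == root_label), , drop = FALSE]
  if (nrow(root_pts) < 2) abort("too few root nuclei to orient a path")
  ctr <- colMeans(root_pts)
  v <- eigen(stats::cov(root_pts))$vectors[, 1]
  branch_pts <- pts[which(labels %in% unlist(branch_labels)), ,
                    drop = FALSE]
  if (sum((colMeans(branch_pts) - ctr) * v) < 0) v <- -v
  proj <- as.numeric((sweep(root_pts, 2, ctr)) %*% v)
  root_start <- ctr + v * quantile(proj, 0.01)
  junction <- ctr + v * quantile(proj, 0.99)
  root <- fit_path(NULL, waypoints = rbind(root_start, junction))

  branches <- lapply(branch_labels, function(cls) {
    bp <- pts[which(labels %in% cls), , drop = FALSE]
    dirb <- apply(bp, 2, median) - junction
    dirb <- dirb / sqrt(sum(dirb^2))
    projb <- as.numeric(sweep(bp, 2, junction) %*% dirb)
    end <- junction + dirb * max(quantile(projb, 0.99), 1e-6)
    fit_path(NULL, waypoints = rbind(junction, end))
  })
  list(root = root, branches = branches)
}

#' Run the full synthetic-to-network pipeline
#'
#' Simulate (or load) a paired multiome dataset, pair nuclei across
#' modalities, impute expression, call and filter peak-to-gene links,
#' identify DARs and markers, run motif enrichment and TF mining, assemble
#' the TF -> cis-element -> target-gene network, and compute supervised
#' branch pseudotime. Every stage's parameters and output sizes are
#' recorded in a provenance log; re-running with an identical configuration
#' reproduces identical outputs (byte-identical files when `out_dir` is
#' set).
#'
#' @param config A [pipeline_config()].
#' @return List with the dataset, pairing, links (full and accepted),
#'   link summary, dars, markers, enrichment, regulator selection, the
#'   `egrn`, pseudotime tibble, and a `provenance` tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  prov <- list()
  log_stage <- function(stage, rows, params = "") {
    if (config$verbose) inform(sprintf("[%s] %d rows %s", stage, rows, params))
    prov[[length(prov) + 1L]] <<- tibble(stage = stage, rows = rows,
                                         params = params)
  }

  ds <- if (!is.null(config$fixture_dir)) {
    if (!dir.exists(config$fixture_dir)) {
      abort(paste0("missing input path: ", config$fixture_dir))
    }
    read_fixture(config$fixture_dir)
  } else {
    simulate_multiome(config$sim)
  }
  log_stage("simulate", ncol(ds$rna) + ncol(ds$atac),
            paste0("seed=", ds$config$seed))

  pairing <- pair_nuclei(ds$latent$atac, ds$latent$rna)
  imputed <- impute_expression(ds$rna, pairing)
  log_stage("pairing", nrow(pairing))

  pairs <- candidate_pairs(ds$genes, ds$peaks,
                           half_width = config$window_half_width)
  links <- pearson_links(imputed, ds$atac, pairs) |>
    filter_links(r_min = config$r_min, q_max = config$q_max)
  accepted <- filter(links, .data$accepted)
  log_stage("linkage", nrow(accepted),
            sprintf("tested=%d r_min=%g q_max=%g", nrow(links),
                    config$r_min, config$q_max))

  atac_truth <- filter(ds$truth, .data$modality == "atac")
  atac_labels <- setNames(atac_truth$true_cluster, atac_truth$nucleus)
  dars <- dar_ttest(ds$atac, atac_labels, p_max = config$dar_p_max,
                    log2fc_min = config$dar_log2fc_min,
                    top_k = config$dar_top_k)
  log_stage("dars", nrow(dars),
            sprintf("p<%g log2FC>=%g", config$dar_p_max,
                    config$dar_log2fc_min))

  rna_truth <- filter(ds$truth, .data$modality == "rna")
  rna_labels <- setNames(rna_truth$true_cluster, rna_truth$nucleus)
  norm_rna <- normalize_log1p(ds$rna)
  markers <- wilcoxon_markers(norm_rna, rna_labels,
                              min_pct = config$min_pct,
                              logfc_min = config$logfc_min)
  log_stage("markers", nrow(markers))

  region_sets <- split(dars$peak_id, dars$group)
  enrich <- motif_enrichment(ds$motif_hits, ds$peaks, region_sets,
                             ds$motif_truth,
                             auc_fraction = config$auc_fraction,
                             min_top = config$min_top)
  enrich_floored <- merge_enrichments(list(enrich),
                                      nes_floor = config$nes_floor)
  mean_expr <- norm_rna |>
    base::t() |>
    rowsum(group = rna_labels[colnames(norm_rna)]) |>
    (\(m) m / as.vector(table(rna_labels[colnames(norm_rna)])))()
  expr_by_cluster <- as_tibble(base::t(mean_expr), rownames = "tf_gene") |>
    tidyr::pivot_longer(-"tf_gene", names_to = "cluster",
                        values_to = "mean_expr")
  corr <- tf_expression_correlation(
    select(enrich, "cluster", "tf_gene", "nes"), expr_by_cluster)
  regulators <- select_regulators(corr, enrich_floored,
                                  per_cluster_top = config$per_cluster_top)
  log_stage("tf_mining", nrow(regulators),
            sprintf("nes_floor=%g", config$nes_floor))

  network <- assemble_egrn(regulators, ds$motif_hits, dars, accepted)
  log_stage("egrn", nrow(network$element_gene))

  pseudotime <- NULL
  if (ds$config$bifurcate) {
    emb <- ds$latent$atac[, 1:2, drop = FALSE]
    cl_a <- sprintf("c%d", 1 + seq_len(ceiling((ds$config$n_clusters - 1) / 2)))
    cl_b <- setdiff(sprintf("c%d", seq_len(ds$config$n_clusters)),
                    c("c1", cl_a))
    paths <- fit_branching_paths(emb, atac_labels, "c1",
                                 list(A = cl_a, B = cl_b))
    pseudotime <- branch_pseudotime(emb, paths$root, paths$branches)
    log_stage("pseudotime", nrow(pseudotime))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(links, file.path(config$out_dir, "links.tsv"))
    if (nrow(network$tfs) > 0) {
      export_network(network, file.path(config$out_dir, "network"))
    }
    if (!is.null(pseudotime)) {
      readr::write_tsv(pseudotime,
                       file.path(config$out_dir, "pseudotime.tsv"))
    }
  }

  list(dataset = ds, pairing = pairing, links = links,
       accepted = accepted, link_summary = link_gene_summary(links),
       dars = dars, markers = markers, enrichment = enrich,
       enrichment_floored = enrich_floored, tf_correlation = corr,
       regulators = regulators, network = network,
       pseudotime = pseudotime, provenance = bind_rows(prov))
}
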