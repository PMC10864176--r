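toy_peaks <- function(n) {
  tibble::tibble(peak_id = sprintf("p%03d", 1:n), chrom = "chr1",
                 start = seq(0, by = 1000, length.out = n)) |>
    dplyr::mutate(end = start + 200)
}

test_that("motif rankings sort by score with the coordinate tie-break", {
  withr::local_seed(51)
  peaks <- toy_peaks(30)
  scores <- tibble::tibble(peak_id = sample(peaks$peak_id, 20),
                           motif_id = "m1",
                           score = runif(20, 1, 10))
  rk <- motif_rankings(scores, peaks)
  full <- setNames(rep(0, 30), peaks$peak_id)
  full[scores$peak_id] <- scores$score
  # explicit argsort oracle on distinct scores (order() is stable, peaks
  # are already in coordinate order)
  expect_identical(rk$m1, peaks$peak_id[order(-full)])

  # all-equal scores fall back to coordinate order; unscored peaks last
  tied <- dplyr::mutate(scores, score = 5)
  rk2 <- motif_rankings(tied, peaks)
  scored <- peaks$peak_id[peaks$peak_id %in% tied$peak_id]
  unscored <- setdiff(peaks$peak_id, scored)
  expect_identical(rk2$m1, c(scored, unscored))

  dup <- dplyr::bind_rows(peaks, peaks[1, ])
  expect_error(motif_rankings(scores, dup), "duplicate")
})

test_that("recovery AUC matches step-curve integration", {
  ranking <- sprintf("p%03d", 1:1000)
  # region set occupying the first k ranks: maximal AUC for that geometry
  top_n <- 20  # max(ceil(0.001*1000), 20)
  rs <- ranking[1:25]
  auc <- recovery_auc(ranking, rs)
  expect_equal(auc, mean(cumsum(rep(TRUE, top_n)) / 25))

  # region set entirely below the top window
  expect_equal(recovery_auc(ranking, ranking[500:520]), 0)

  # random set against an explicit cumulative-sum oracle
  withr::local_seed(52)
  rs2 <- sample(ranking, 60)
  oracle <- {
    hits <- ranking[1:top_n] %in% rs2
    rec <- cumsum(hits) / 60
    mean(rec)
  }
  expect_equal(recovery_auc(ranking, rs2), oracle, tolerance = 1e-12)
  expect_error(recovery_auc(ranking, character(0)), "empty")
})

test_that("NES scores are exact z-scores", {
  nes <- nes_scores(c(a = 0.1, b = 0.2, c = 0.3))
  expect_equal(mean(nes), 0, tolerance = 1e-12)
  expect_equal(sd(nes), 1, tolerance = 1e-12)
  expect_equal(unname(nes), c(-1, 0, 1))

  withr::local_seed(53)
  aucs <- setNames(runif(200), sprintf("m%03d", 1:200))
  nes2 <- nes_scores(aucs)
  expect_equal(unname(nes2), unname((aucs - mean(aucs)) / sd(aucs)),
               tolerance = 1e-12)
  perm <- sample(names(aucs))
  expect_equal(nes_scores(aucs[perm]), nes2[perm])
  expect_error(nes_scores(c(a = 1, b = 1, c = 1)), "zero")
})

test_that("merging enrichment tables keeps the maximal NES above the floor", {
  t1 <- tibble::tibble(cluster = "c1", motif_id = c("m1", "m2"),
                       tf_gene = c("tfA", "tfB"), auc = c(0.5, 0.4),
                       nes = c(2.9, 5), source = "s1")
  t2 <- tibble::tibble(cluster = "c1", motif_id = "m1", tf_gene = "tfA",
                       auc = 0.6, nes = 3.4, source = "s2")
  merged <- merge_enrichments(list(t1, t2))
  expect_equal(merged$nes[merged$motif_id == "m1"], 3.4)
  expect_equal(nrow(merged), 2)

  single <- merge_enrichments(list(t1), nes_floor = -Inf)
  expect_equal(nrow(single), 2)
  expect_equal(nrow(merge_enrichments(list(t1), nes_floor = 10)), 0)

  conflict <- dplyr::mutate(t2, tf_gene = "tfZ")
  expect_error(merge_enrichments(list(t1, conflict)), "m1")
})

test_that("NES-expression correlation matches cor() and ranks proportional TFs first", {
  nes <- tidyr::expand_grid(cluster = c("c1", "c2", "c3", "c4"),
                            tf_gene = c("up", "down")) |>
    dplyr::mutate(nes = c(1, -1, 2, -2, 3, -3, 4, -4))
  expr <- dplyr::mutate(nes, mean_expr = ifelse(tf_gene == "up", nes, 5),
                        nes = NULL)
  expr$mean_expr[expr$tf_gene == "down"] <- c(1, 2, 3, 4)  # anti-proportional
  corr <- tf_expression_correlation(nes, expr)
  expect_equal(corr$r[corr$tf_gene == "up"], 1)
  expect_equal(corr$rank[corr$tf_gene == "up"], 1L)
  expect_equal(corr$r[corr$tf_gene == "down"], -1)
  expect_equal(corr$rank[corr$tf_gene == "down"], 2L)

  withr::local_seed(54)
  rnd_nes <- tidyr::expand_grid(cluster = sprintf("c%d", 1:6),
                                tf_gene = sprintf("tf%d", 1:8)) |>
    dplyr::mutate(nes = rnorm(48))
  rnd_expr <- dplyr::mutate(rnd_nes, mean_expr = rnorm(48), nes = NULL)
  corr2 <- tf_expression_correlation(rnd_nes, rnd_expr)
  for (tf in corr2$tf_gene) {
    a <- dplyr::filter(rnd_nes, tf_gene == tf) |> dplyr::arrange(cluster)
    b <- dplyr::filter(rnd_expr, tf_gene == tf) |> dplyr::arrange(cluster)
    expect_equal(corr2$r[corr2$tf_gene == tf], cor(a$nes, b$mean_expr),
                 tolerance = 1e-12)
  }
})

test_that("regulator selection requires positive correlation and the NES floor", {
  corr <- tibble::tibble(tf_gene = c("pos", "neg", "zero"),
                         r = c(0.8, -0.5, 0), n_clusters = 3, rank = 1:3)
  nes <- tibble::tibble(cluster = "c1", motif_id = paste0("m_", corr$tf_gene),
                        tf_gene = corr$tf_gene, auc = 0.5, nes = 5,
                        source = "s")
  sel <- select_regulators(corr, nes)
  expect_identical(sel$tf_gene, "pos")
})

test_that("network assembly recovers planted triples and respects link locality", {
  cfg <- small_config(seed = 3, noise_sd = 0.05, nb_dispersion = 10)
  res <- suppressWarnings(run_pipeline(pipeline_config(sim = cfg)))
  ds <- res$dataset
  triples <- dplyr::distinct(ds$programs, tf_gene, enhancer_peak,
                             target_gene)
  found <- dplyr::inner_join(
    triples, res$network$element_gene,
    by = c(tf_gene = "tf_gene", enhancer_peak = "peak_id",
           target_gene = "gene_id"))
  expect_gte(nrow(found), ceiling(0.8 * nrow(triples)))

  # removing one accepted link removes exactly its element->gene edge
  drop <- res$network$element_gene[1, ]
  acc2 <- dplyr::anti_join(res$accepted, drop,
                           by = c("peak_id", "gene_id"))
  atac_truth <- dplyr::filter(ds$truth, modality == "atac")
  net2 <- assemble_egrn(res$regulators, ds$motif_hits, res$dars, acc2)
  gone <- dplyr::anti_join(res$network$element_gene, net2$element_gene,
                           by = c("cluster", "tf_gene", "peak_id",
                                  "gene_id"))
  expect_equal(nrow(gone),
               sum(res$network$element_gene$peak_id == drop$peak_id &
                     res$network$element_gene$gene_id == drop$gene_id))

  # a TF whose motif hits no DAR is omitted
  fake_sel <- tibble::tibble(cluster = "c1", tf_gene = "ghost",
                             motif_id = "motif_ghost", nes = 9, r = 0.9)
  hits <- dplyr::bind_rows(ds$motif_hits,
                           tibble::tibble(peak_id = "peak_absent",
                                          motif_id = "motif_ghost",
                                          score = 9))
  net3 <- assemble_egrn(fake_sel, hits, res$dars, res$accepted)
  expect_equal(nrow(net3$tfs), 0)

  expect_error(
    assemble_egrn(fake_sel, ds$motif_hits, res$dars, res$accepted),
    "motif_ghost"
  )
})

test_that("network export and import round-trip the graph exactly", {
  ds <- small_multiome()
  res <- suppressWarnings(run_pipeline(pipeline_config(sim = ds$config)))
  dir <- withr::local_tempdir()
  export_network(res$network, dir)
  expect_true(file.exists(file.path(dir, "network.sif")))
  back <- import_network(dir)
  expect_equal(as.data.frame(back$tf_element),
               as.data.frame(res$network$tf_element))
  expect_equal(as.data.frame(back$element_gene),
               as.data.frame(res$network$element_gene))
  g1 <- egrn_igraph(res$network); g2 <- egrn_igraph(back)
  expect_true(igraph::identical_graphs(g1, g2) ||
                isTRUE(all.equal(igraph::as_data_frame(g1),
                                 igraph::as_data_frame(g2))))

  empty <- structure(list(tfs = tibble::tibble()), class = "egrn")
  expect_error(export_network(empty, dir), "empty")
})
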