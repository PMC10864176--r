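test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- small_config(seed = 21)
  a <- simulate_multiome(cfg)
  b <- simulate_multiome(cfg)
  expect_identical(as.matrix(a$rna), as.matrix(b$rna))
  expect_identical(as.matrix(a$atac), as.matrix(b$atac))
  expect_identical(a$latent, b$latent)
  expect_identical(a$truth, b$truth)
  expect_identical(a$motif_hits, b$motif_hits)
})

test_that("zero latent noise puts nuclei exactly on the path and pseudotime is recovered", {
  cfg <- small_config(seed = 4, noise_sd = 0)
  lat <- simulate_trajectory_latent(cfg)
  root <- fit_path(NULL, waypoints = lat$paths$root)
  branches <- lapply(lat$paths[c("A", "B")], function(wp)
    fit_path(NULL, waypoints = wp))
  for (mod in c("rna", "atac")) {
    emb <- lat$latent[[mod]][, 1:2]
    tr <- dplyr::filter(lat$truth, modality == mod)
    bp <- branch_pseudotime(emb, root, branches)
    j <- dplyr::inner_join(bp, tr, by = "nucleus")
    expect_lt(max(j$distance), 1e-9)
    for (b in c("A", "B")) {
      jb <- dplyr::filter(j, true_branch == b)
      expect_equal(cor(jb$t, jb$true_pseudotime, method = "spearman"), 1)
    }
  }
})

test_that("branch labels are recoverable by nearest-path assignment at noise 0.1", {
  cfg <- sim_config(n_rna_nuclei = 500, n_atac_nuclei = 10, n_genes = 60,
                    n_peaks = 200, targets_per_tf = 3, decoy_motifs = 10,
                    noise_sd = 0.1, seed = 8)
  lat <- simulate_trajectory_latent(cfg)
  tr <- dplyr::filter(lat$truth, modality == "rna", true_branch != "root")
  emb <- lat$latent$rna[tr$nucleus, 1:2]
  # brute-force nearest-segment assignment against the generating geometry
  seg_dist <- function(p, a, b) {
    ab <- b - a; tt <- sum((p - a) * ab) / sum(ab^2)
    tt <- min(max(tt, 0), 1)
    sqrt(sum((p - (a + tt * ab))^2))
  }
  assigned <- apply(emb, 1, function(p) {
    dA <- seg_dist(p, lat$paths$A[1, ], lat$paths$A[2, ])
    dB <- seg_dist(p, lat$paths$B[1, ], lat$paths$B[2, ])
    if (dA <= dB) "A" else "B"
  })
  expect_gte(mean(assigned == tr$true_branch), 0.95)
})

test_that("planted enhancers sit inside their target's linkage window", {
  ds <- small_multiome()
  hw <- ds$config$window_half_width
  pk <- ds$peaks
  mid <- floor((pk$start + pk$end) / 2)
  names(mid) <- pk$peak_id
  for (i in seq_len(nrow(ds$programs))) {
    tss <- ds$genes$tss[ds$genes$gene_id == ds$programs$target_gene[i]]
    m <- mid[[ds$programs$enhancer_peak[i]]]
    expect_true(m >= tss - hw && m < tss + hw)
  }
})

test_that("motif truth is a bijection and decoy window membership matches its rate", {
  ds <- small_multiome()
  expect_false(any(duplicated(ds$motif_truth$motif_id)))
  expect_false(any(duplicated(ds$motif_truth$tf_gene)))

  # brute-force window membership of decoy peaks
  dec <- dplyr::filter(ds$peaks, type != "enhancer")
  mid <- floor((dec$start + dec$end) / 2)
  hw <- ds$config$window_half_width
  inside <- vapply(mid, function(m) {
    any(m >= ds$genes$tss - hw & m < ds$genes$tss + hw)
  }, logical(1))
  phat <- mean(inside)
  p0 <- ds$config$decoy_inside_frac
  se <- sqrt(p0 * (1 - p0) / nrow(dec))
  expect_lt(abs(phat - p0), 4 * se)
  expect_identical(sort(unique(dec$type[inside])), "decoy_inside")
})

test_that("the Poisson limit flag gives variance approximately equal to the mean", {
  # almost every gene in a program with zero effect -> flat per-gene rates,
  # so the variance/mean ratio isolates the count noise model
  flat_cfg <- function(...) {
    sim_config(n_rna_nuclei = 120, n_atac_nuclei = 20, n_genes = 64,
               n_peaks = 200, n_tf_programs = 3, targets_per_tf = 20,
               decoy_motifs = 1, effect_size = 0, seed = 10, ...)
  }
  ds <- simulate_multiome(flat_cfg(poisson_rna = TRUE))
  prog <- ds$genes$gene_id[ds$genes$role != "background"]
  m <- as.matrix(ds$rna)
  ratio <- apply(m[prog, ], 1, var) / rowMeans(m[prog, ])
  expect_lt(abs(median(ratio) - 1), 0.25)

  ds_nb <- simulate_multiome(flat_cfg(nb_dispersion = 0.5))
  m_nb <- as.matrix(ds_nb$rna)
  ratio_nb <- apply(m_nb[prog, ], 1, var) / rowMeans(m_nb[prog, ])
  expect_gt(median(ratio_nb), 2)  # overdispersed by construction
})

test_that("count matrices have the configured shape and integer non-negative values", {
  ds <- small_multiome()
  expect_identical(dim(ds$rna), c(60L, 80L))
  expect_identical(dim(ds$atac), c(200L, 80L))
  expect_true(all(ds$rna@x >= 0), all(ds$rna@x == round(ds$rna@x)))
  expect_true(all(ds$atac@x >= 0))
})

test_that("fixtures round-trip exactly and identical seeds give identical bytes", {
  ds <- simulate_multiome(small_config(seed = 33))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(ds, file.path(d1, "fx"))
  write_fixture(ds, file.path(d2, "fx"))

  back <- read_fixture(file.path(d1, "fx"))
  expect_identical(as.matrix(back$rna), as.matrix(ds$rna))
  expect_identical(as.matrix(back$atac), as.matrix(ds$atac))
  expect_equal(back$planted_links, ds$planted_links)

  f1 <- list.files(file.path(d1, "fx"), recursive = TRUE)
  expect_identical(
    unname(tools::md5sum(file.path(d1, "fx", f1))),
    unname(tools::md5sum(file.path(d2, "fx", f1)))
  )

  # BED contract
  bed <- read_bed(file.path(d1, "fx", "peaks.bed"))
  expect_true(all(bed$start < bed$end))
  expect_equal(bed$start, ds$peaks$start)

  expect_error(write_fixture(ds, file.path(d1, "fx")), "non-empty")
})

test_that("fragment draws are consistent with the counts they came from", {
  cfg <- sim_config(n_rna_nuclei = 20, n_atac_nuclei = 20, n_genes = 30,
                    n_peaks = 80, targets_per_tf = 2, decoy_motifs = 5,
                    atac_depth_mean = 100, seed = 6)
  ds <- simulate_multiome(cfg)
  fr <- simulate_fragments(ds)
  expect_identical(nrow(fr), as.integer(sum(ds$atac)))
  expect_true(all(fr$start < fr$end))
  # every fragment lies inside some peak
  ov <- overlap_percentage(fr[, c("chrom", "start", "end")], ds$peaks)
  expect_equal(ov$fraction, 1)
})
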