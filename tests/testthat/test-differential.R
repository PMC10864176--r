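test_that("wilcoxon marker p-values match exhaustive permutation enumeration", {
  # 4 vs 4, no ties: enumerate all label reassignments of the pooled values
  x <- c(5.1, 4.8, 6.2, 5.9)   # group A (clearly higher, passes filters)
  y <- c(1.2, 0.7, 2.1, 1.5)
  mat <- matrix(c(x, y), 1, 8,
                dimnames = list("f1", sprintf("n%d", 1:8)))
  labels <- setNames(rep(c("A", "B"), each = 4), colnames(mat))
  res <- wilcoxon_markers(mat, labels, min_pct = 0, logfc_min = -Inf)
  pA <- res$p[res$group == "A"]

  pooled <- c(x, y)
  combos <- combn(8, 4)
  r_all <- rank(pooled)
  W <- apply(combos, 2, function(ix) sum(r_all[ix]) - 4 * 5 / 2)
  w_obs <- sum(r_all[1:4]) - 4 * 5 / 2
  p_lo <- mean(W <= w_obs); p_hi <- mean(W >= w_obs)
  p_exact <- min(1, 2 * (if (w_obs > 4 * 4 / 2) p_hi else p_lo))
  expect_equal(pA, p_exact, tolerance = 1e-10)
})

test_that("wilcoxon markers apply detection and fold-change filters", {
  withr::local_seed(41)
  n <- 40
  mat <- rbind(
    rare = rep(c(2, rep(0, 19)), 2),      # exactly 5% detection per side
    same = rnorm(n, 1, 0.01)              # identical distributions, no FC
  )
  colnames(mat) <- sprintf("n%02d", 1:n)
  labels <- setNames(rep(c("A", "B"), each = n / 2), colnames(mat))
  res <- wilcoxon_markers(mat, labels, min_pct = 0.1, logfc_min = 0.25)
  expect_false("rare" %in% res$feature)   # below min.pct on both sides
  expect_false("same" %in% res$feature)   # identical distributions, no FC
})

test_that("anova markers reduce to the squared-t test for two groups", {
  withr::local_seed(42)
  x <- rnorm(12, 4); y <- rnorm(10, 2)
  mat <- matrix(c(x, y), 1, 22,
                dimnames = list("f1", sprintf("n%02d", 1:22)))
  labels <- setNames(rep(c("A", "B"), c(12, 10)), colnames(mat))
  res <- anova_markers(mat, labels, fc_min = 0, p_max = 1)
  expect_equal(res$p, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("anova F statistic matches hand-computed sums of squares", {
  vals <- list(A = c(1, 2, 3), B = c(4, 6, 5, 7), C = c(9, 8, 10))
  x <- unlist(vals)
  g <- rep(names(vals), lengths(vals))
  mat <- matrix(x, 1, length(x),
                dimnames = list("f1", sprintf("n%02d", seq_along(x))))
  labels <- setNames(g, colnames(mat))
  res <- anova_markers(mat, labels, fc_min = 0, p_max = 1)

  grand <- mean(x)
  ss_between <- sum(lengths(vals) *
                      (vapply(vals, mean, numeric(1)) - grand)^2)
  ss_within <- sum(unlist(lapply(vals, function(v) (v - mean(v))^2)))
  df1 <- 3 - 1; df2 <- length(x) - 3
  f_hand <- (ss_between / df1) / (ss_within / df2)
  expect_equal(res$p, pf(f_hand, df1, df2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$group, "C")  # focal group = highest mean
})

test_that("anova type-I error tracks the nominal level under the null", {
  withr::local_seed(43)
  n_feat <- 400
  # values on a normalized-counts-like scale (positive), equal group means
  mat <- matrix(rnorm(n_feat * 30, mean = 5), n_feat, 30,
                dimnames = list(sprintf("f%03d", 1:n_feat),
                                sprintf("n%02d", 1:30)))
  labels <- setNames(rep(c("A", "B", "C"), each = 10), colnames(mat))
  res <- anova_markers(mat, labels, fc_min = 0, p_max = 0.05)
  rate <- nrow(dplyr::filter(res, !is.na(p))) / n_feat
  expect_lt(abs(rate - 0.05), 0.03)
})

test_that("consensus of top-N lists is an exact set intersection", {
  mk <- function(features) {
    tibble::tibble(feature = features, rank = seq_along(features))
  }
  t1 <- mk(sprintf("g%03d", 1:300))
  expect_setequal(consensus_top200(list(t1, t1)), sprintf("g%03d", 1:200))
  t2 <- mk(sprintf("h%03d", 1:300))
  expect_length(consensus_top200(list(t1, t2)), 0)

  withr::local_seed(44)
  universe <- sprintf("g%03d", 1:300)
  tabs <- lapply(1:3, function(i) mk(sample(universe)))
  got <- consensus_top200(tabs, top_n = 100)
  oracle <- Reduce(intersect, lapply(tabs, function(tb) tb$feature[1:100]))
  expect_setequal(got, oracle)
  expect_warning(consensus_top200(list(mk(universe[1:50]), t1)), "shorter")
})

test_that("DAR t-test detects a planted peak and stays empty under the null", {
  withr::local_seed(45)
  n <- 60
  counts <- matrix(rpois(100 * n, 5), 100, n,
                   dimnames = list(sprintf("p%03d", 1:100),
                                   sprintf("n%02d", 1:n)))
  labels <- setNames(rep(c("A", "B"), each = n / 2), colnames(counts))
  counts["p001", labels == "A"] <- rpois(n / 2, 40)  # rate x8
  dars <- dar_ttest(counts, labels)
  expect_true("p001" %in% dars$peak_id[dars$group == "A"])

  empty_runs <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      null_counts <- matrix(rpois(100 * n, 5), 100, n,
                            dimnames = dimnames(counts))
      nrow(dar_ttest(null_counts, labels)) == 0
    })
  }, logical(1))
  expect_gte(mean(empty_runs), 0.95)
})

test_that("DAR sets are truncated to top_k by rank", {
  withr::local_seed(46)
  n <- 40
  counts <- matrix(rpois(30 * n, 2), 30, n,
                   dimnames = list(sprintf("p%02d", 1:30),
                                   sprintf("n%02d", 1:n)))
  labels <- setNames(rep(c("A", "B"), each = n / 2), colnames(counts))
  counts[, labels == "A"] <- matrix(rpois(30 * n / 2, 20), 30)
  full <- dar_ttest(counts, labels, top_k = 5000)
  expect_gt(nrow(dplyr::filter(full, group == "A")), 10)
  cut <- dar_ttest(counts, labels, top_k = 10)
  cutA <- dplyr::filter(cut, group == "A")
  expect_identical(nrow(cutA), 10L)
  expect_identical(cutA$peak_id,
                   dplyr::filter(full, group == "A")$peak_id[1:10])
})

test_that("fisher enrichment equals the hypergeometric tail by enumeration", {
  universe <- sprintf("u%02d", 1:10)
  query <- universe[1:5]
  terms <- list(tm = universe[c(1, 2, 3, 6)])
  res <- fisher_enrichment(query, terms, universe)

  # exhaustive tail: P(overlap >= 3) with N=10, K=4, n=5
  N <- 10; K <- 4; n <- 5; k <- 3
  p_enum <- sum(vapply(k:min(K, n), function(j) {
    choose(K, j) * choose(N - K, n - j) / choose(N, n)
  }, numeric(1)))
  expect_equal(res$p, p_enum, tolerance = 1e-12)
  ft <- fisher.test(matrix(c(3, 1, 2, 4), 2, 2), alternative = "greater")
  expect_equal(res$p, ft$p.value, tolerance = 1e-12)

  disj <- fisher_enrichment(universe[1:3], list(tm = universe[8:10]),
                            universe)
  expect_equal(disj$p, 1)
  expect_error(fisher_enrichment(character(0), terms, universe), "empty")
})

test_that("marker q-values reproduce a brute-force BH oracle", {
  withr::local_seed(47)
  mat <- matrix(rnorm(200 * 24), 200, 24,
                dimnames = list(sprintf("f%03d", 1:200),
                                sprintf("n%02d", 1:24)))
  mat[1:20, 1:12] <- mat[1:20, 1:12] + 2
  labels <- setNames(rep(c("A", "B"), each = 12), colnames(mat))
  # negative-mean features yield NaN fold changes by design here; they are
  # excluded from testing, which is the behaviour under scrutiny
  res <- suppressWarnings(
    wilcoxon_markers(mat, labels, min_pct = 0, logfc_min = -Inf))
  for (g in c("A", "B")) {
    sub <- dplyr::filter(res, group == g)
    ord <- order(sub$p)
    m <- nrow(sub)
    q_oracle <- rev(cummin(rev(sub$p[ord] * m / seq_len(m))))
    expect_equal(sub$q[ord], pmin(q_oracle, 1), tolerance = 1e-12)
  }
})
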