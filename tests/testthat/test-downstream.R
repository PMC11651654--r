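test_that("binding matrix equals a brute-force overlap table and filters columns", {
  dhs <- data.table::data.table(chrom = "chrS",
    start = c(1000L, 5000L, 9000L, 13000L, 17000L),
    end = c(1300L, 5300L, 9300L, 13300L, 17300L),
    name = paste0("d", 1:5))
  trf <- list(
    A = data.table::data.table(chrom = "chrS", start = c(900L, 5100L),
                               end = c(1100L, 5200L)),
    B = data.table::data.table(chrom = "chrS", start = 17000L, end = 17050L),
    C = data.table::data.table(chrom = "chrS", start = 40000L, end = 40300L))
  m <- build_binding_matrix(dhs, trf, min_bound = 0L)
  oracle <- matrix(0L, 5, 3, dimnames = list(paste0("d", 1:5), c("A", "B", "C")))
  oracle["d1", "A"] <- 1L; oracle["d2", "A"] <- 1L; oracle["d5", "B"] <- 1L
  expect_equal(m[, c("A", "B")], oracle[, c("A", "B")])
  expect_false("C" %in% colnames(m))     # bound to 0 > min_bound 0 fails
  # column selection: bound count strictly > min_bound, enrichment > min_enrich
  enr <- data.table::data.table(feature = c("A", "B"),
                                log2_enrichment = c(2.1, 1.0))
  m2 <- build_binding_matrix(dhs, trf, enrichment = enr, min_bound = 1L,
                             min_enrich = 2)
  expect_equal(colnames(m2), "A")        # B fails both rules
})

make_blocks <- function(n_per, k, n_trf, flip = 0, seed = 1) {
  set.seed(seed)
  proto <- matrix(0L, k, n_trf)
  for (c in seq_len(k))
    proto[c, ((c - 1) * (n_trf %/% k) + 1):(c * (n_trf %/% k))] <- 1L
  rows <- proto[rep(seq_len(k), each = n_per), ]
  noise <- matrix(runif(length(rows)) < flip, nrow(rows))
  rows <- abs(rows - noise)
  rownames(rows) <- paste0("d", seq_len(nrow(rows)))
  colnames(rows) <- paste0("TRF", seq_len(n_trf))
  list(mat = rows, truth = rep(seq_len(k), each = n_per))
}

test_that("Ward clustering recovers planted binary blocks", {
  skip_if_not_installed("mclust")
  # two clean blocks
  b2 <- make_blocks(25, 2, 12, flip = 0, seed = 2)
  cl2 <- cluster_dhs(b2$mat, k = 2)
  expect_equal(mclust::adjustedRandIndex(cl2$assignment$cluster, b2$truth), 1)
  # four blocks with 5% bit-flip noise
  b4 <- make_blocks(40, 4, 24, flip = 0.05, seed = 3)
  cl4 <- cluster_dhs(b4$mat, k = 4)
  expect_gte(mclust::adjustedRandIndex(cl4$assignment$cluster, b4$truth), 0.9)
  # row-order invariance (same partition up to labels)
  perm <- sample(nrow(b4$mat))
  cl4p <- cluster_dhs(b4$mat[perm, ], k = 4)
  reord <- cl4p$assignment$cluster[match(cl4$assignment$dhs_id,
                                         cl4p$assignment$dhs_id)]
  expect_equal(mclust::adjustedRandIndex(cl4$assignment$cluster, reord), 1)
  # identical rows in one cluster
  same <- matrix(1L, 10, 5, dimnames = list(paste0("d", 1:10), paste0("t", 1:5)))
  expect_equal(unique(cluster_dhs(same, k = 1)$assignment$cluster), 1L)
  expect_error(cluster_dhs(same, k = 11), "exceeds")
  # per-cluster top-TRF summary ranks factors by bound-DHS count
  expect_length(cl2$top_trfs, 2)
  for (c in 1:2) {
    sub <- b2$mat[cl2$assignment$cluster == c, , drop = FALSE]
    expect_setequal(cl2$top_trfs[[c]][1:6],
                    names(which(colSums(sub) == nrow(sub))))
  }
  expect_setequal(cl2$top_union, colnames(b2$mat))
})

test_that("cluster enhancer test matches the exact binomial tail", {
  # direct worked examples on constructed overlap patterns
  mkdhs <- function(n) data.table::data.table(
    chrom = "chrS", start = 1000L * seq_len(n), end = 1000L * seq_len(n) + 300L,
    name = paste0("d", seq_len(n)))
  dhs <- mkdhs(20)
  assignment <- data.table::data.table(dhs_id = dhs$name,
                                       cluster = rep(1:2, each = 10))
  # enhancers overlap DHSs 1..5 (cluster 1) and 11..15 (cluster 2): x=5, n=10
  enh <- dhs[c(1:5, 11:15), .(chrom, start, end)]
  res <- cluster_enhancer_test(assignment, dhs, enh)
  # p0 = 10/20 = 0.5; P(X >= 5 | Bin(10, 0.5)) = 0.6230
  expect_equal(res$p_value, c(0.623046875, 0.623046875), tolerance = 1e-12)
  # all enhancers in one cluster: x = n = 10, p = 0.5^10
  enh1 <- dhs[1:10, .(chrom, start, end)]
  res1 <- cluster_enhancer_test(assignment, dhs, enh1)
  expect_equal(res1$p_value[1], 0.5^10)
  expect_equal(res1$p_value[2], 1)   # x = 0 -> p = 1
  # brute-force tail-sum oracle on random cases
  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:1000, 1); x <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    oracle <- sum(choose(n, x:n) * p0^(x:n) * (1 - p0)^(n - (x:n)))
    expect_equal(pbinom(x - 1, n, p0, lower.tail = FALSE), oracle,
                 tolerance = 1e-8)
  }
  # unmapped enhancers are counted
  enh_un <- rbind(enh1, data.table::data.table(chrom = "chrS",
    start = 900000L, end = 900300L))
  expect_equal(attr(cluster_enhancer_test(assignment, dhs, enh_un),
                    "n_unmapped"), 1L)
})

test_that("greedy forward selection finds the causal feature first", {
  ft <- simulate_feature_table(n_pairs = 600, n_candidates = 10,
                               causal = "cand03", effect = 2, seed = 31)
  base <- c("distance", "ctcf_vp_signal", "ctcf_dhs_signal",
            "vp_motif_fwd", "vp_motif_rev", "dhs_motif_fwd", "dhs_motif_rev")
  sel <- greedy_rf_selection(ft$table, target = "signal",
                             base_features = base,
                             candidates = sprintf("cand%02d", 1:10),
                             n_add = 2, seed = 11)
  expect_equal(sel$selected[1], "cand03")
  expect_equal(nrow(sel$trace), 2L)
  expect_gt(sel$trace$score[1], 0.3)
  # reproducibility under the same seed
  sel2 <- greedy_rf_selection(ft$table, target = "signal",
                              base_features = base,
                              candidates = sprintf("cand%02d", 1:10),
                              n_add = 2, seed = 11)
  expect_identical(sel$selected, sel2$selected)
  expect_identical(sel$trace$score, sel2$trace$score)
})

test_that("constant targets score ~0 R2 and noise targets ~0.5 AUC", {
  ft <- simulate_feature_table(n_pairs = 300, n_candidates = 4,
                               causal = "cand01", effect = 0, seed = 5)
  tab <- ft$table
  tab$signal <- 1.0       # constant target: no variance to explain
  sel <- greedy_rf_selection(tab, target = "signal",
                             base_features = c("distance"),
                             candidates = sprintf("cand%02d", 1:4),
                             n_add = 1, seed = 2)
  expect_lt(abs(sel$trace$score[1]), 1e-9)
  # pure-noise binary target: AUC near 0.5
  tab2 <- ft$table
  tab2$signal <- rnorm(nrow(tab2))
  tab2$distance <- runif(nrow(tab2))   # break the decay signal too
  sel2 <- greedy_rf_selection(tab2, target = "signal",
                              base_features = c("distance"),
                              candidates = sprintf("cand%02d", 1:4),
                              n_add = 1, mode = "classification", seed = 3)
  expect_lt(abs(sel2$trace$score[1] - 0.5), 0.12)
  # fewer candidates than n_add warns and selects all
  expect_warning(
    sel3 <- greedy_rf_selection(ft$table, target = "signal",
                                base_features = c("distance"),
                                candidates = c("cand01", "cand02"),
                                n_add = 5, seed = 4), "fewer candidates")
  expect_length(sel3$selected, 2)
})

test_that("IQR outlier filtering drops only extreme upper values", {
  vals <- c(1:100, 10000)
  keep <- iqr_outlier_filter(vals, t = 50)
  expect_equal(which(!keep), 101L)
  # quartile arithmetic: Q3 = 76, IQR = 50, cutoff = 76 + 50*50 = 2576
  expect_true(all(vals[keep] <= 2576))
  expect_warning(k2 <- iqr_outlier_filter(rep(5, 10)), "zero IQR")
  expect_true(all(k2))
  expect_true(all(iqr_outlier_filter(c(1, 2, 3, 1e9), t = Inf)))
  expect_error(iqr_outlier_filter(c(1, 2, 3)), "at least 4")
})

test_that("coverage correlation over regions hits the closed form", {
  sizes <- c(chrS = 100000L)
  regions <- data.table::data.table(chrom = "chrS",
    start = seq(0L, 40000L, by = 10000L),
    end = seq(1000L, 41000L, by = 10000L))
  depth_track <- function(depths) {
    frags <- data.table::rbindlist(lapply(seq_along(depths), function(i)
      if (depths[i] > 0) data.table::data.table(chrom = "chrS",
        start = rep(regions$start[i], depths[i]),
        end = rep(regions$end[i], depths[i])) else NULL))
    coverage_track(frags, sizes)
  }
  a <- depth_track(c(1, 2, 3, 4, 5))
  expect_equal(coverage_correlation(a, a, regions), 1.0)
  b <- depth_track(c(5, 4, 3, 2, 1))     # b = -a + 6: anti-correlated
  expect_equal(coverage_correlation(a, b, regions), -1.0)
  # hand-built case against the closed-form Pearson
  c_ <- depth_track(c(2, 1, 4, 3, 5))
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- sum((x - 3) * (y - 3)) / sqrt(sum((x - 3)^2) * sum((y - 3)^2))
  expect_equal(coverage_correlation(a, c_, regions), r)
  expect_error(coverage_correlation(a, depth_track(c(2, 2, 2, 2, 2)), regions),
               "zero variance")
})
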