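# interactions on one chromosome: viewpoint interval + other-end bin
mk_inter <- function(vp_center, bin_start, chrom = "chrS") {
  data.table::data.table(
    chrom = chrom, viewpoint_id = seq_along(vp_center),
    vp_start = as.integer(vp_center - 500),
    vp_end = as.integer(vp_center + 500),
    bin_start = as.integer(bin_start),
    bin_end = as.integer(bin_start + 250L))
}

sizes <- c(chrS = 2e7)

test_that("permutation preserves the |distance| multiset and is seeded", {
  set.seed(3)
  vpc <- sample(seq(3e6, 17e6, by = 1e5), 100)
  d <- sample(c(-1, 1), 100, TRUE) * round(runif(100, 1e4, 5e5))
  inter <- mk_inter(vpc, (vpc + d) %/% 250 * 250)
  perms <- permute_pirs(inter, n_perm = 20, seed = 5, chrom_sizes = sizes)
  expect_length(perms, 20)
  obs_d <- sort(abs((inter$bin_start + inter$bin_end) / 2 -
                      (inter$vp_start + inter$vp_end) / 2))
  if (attr(perms, "n_redrawn") == 0) {
    for (p in perms[1:5]) {
      pd <- sort(abs((p$start + p$end) / 2 -
                       (inter$vp_start + inter$vp_end) / 2))
      # multiset preserved up to bin-grid snapping (< 250 bp per entry)
      expect_lt(max(abs(pd - obs_d)), 250)
    }
  }
  # mean permuted |distance| within 1% of observed
  all_pd <- unlist(lapply(perms, function(p)
    abs((p$start + p$end) / 2 - (inter$vp_start + inter$vp_end) / 2)))
  expect_lt(abs(mean(all_pd) - mean(obs_d)) / mean(obs_d), 0.01)
  # determinism
  perms2 <- permute_pirs(inter, n_perm = 20, seed = 5, chrom_sizes = sizes)
  expect_identical(perms, perms2)
  # a singleton interaction keeps its distance
  one <- mk_inter(5e6, 5e6 + 30000)
  p1 <- permute_pirs(one, n_perm = 3, seed = 1, chrom_sizes = sizes)
  expect_true(all(vapply(p1, function(p) p$start, 0L) == one$bin_start))
})

test_that("feature enrichment is 0 for genome-tiling features and exact for ratios", {
  pirs <- data.table::data.table(chrom = "chrS",
                                 start = seq(1e6, 2e6, by = 1e5),
                                 end = seq(1e6, 2e6, by = 1e5) + 250)
  tiling <- data.table::data.table(chrom = "chrS", start = 0L, end = 2e7)
  fake_perms <- rep(list(pirs), 10)
  res <- feature_enrichment(pirs, tiling, fake_perms, name = "tile")
  expect_equal(res$observed, nrow(pirs))
  expect_equal(res$expected_mean, nrow(pirs))
  expect_equal(res$log2_enrichment, 0)

  # observed = 4 x expected -> log2 = 2 (construct permutations that hit 1/4)
  feat <- data.table::data.table(chrom = "chrS", start = c(1e6, 1.1e6, 1.2e6,
    1.3e6), end = c(1e6, 1.1e6, 1.2e6, 1.3e6) + 250)
  hit1 <- data.table::copy(pirs)[, `:=`(start = start + 5e6, end = end + 5e6)]
  hit1$start[1] <- 1e6; hit1$end[1] <- 1e6 + 250
  res2 <- feature_enrichment(pirs[1:4], feat, rep(list(hit1[1:4]), 5))
  expect_equal(res2$observed, 4L)
  expect_equal(res2$expected_mean, 1)
  expect_equal(res2$log2_enrichment, 2)
})

test_that("uniform-feature enrichment matches the Poisson approximation", {
  set.seed(9)
  n_feat <- 4000; wf <- 200; w <- 250; G <- 2e7
  feats <- data.table::data.table(
    chrom = "chrS", start = sort(round(runif(n_feat, 0, G - wf))))
  feats[, end := start + wf]
  vpc <- sample(seq(3e6, 17e6, by = 5e4), 200)
  d <- sample(c(-1, 1), 200, TRUE) * round(runif(200, 1e4, 1e6))
  inter <- mk_inter(vpc, (vpc + d) %/% 250 * 250)
  pirs <- inter[, .(chrom, start = bin_start, end = bin_end)]
  perms <- permute_pirs(inter, n_perm = 50, seed = 21, chrom_sizes = sizes)
  res <- feature_enrichment(pirs, feats, perms)
  # P(a random bin overlaps >= 1 uniform feature) ~ 1 - exp(-density*(w+wf))
  p_hit <- 1 - exp(-n_feat / G * (w + wf - 1))
  expected <- nrow(pirs) * p_hit
  sd3 <- 3 * sqrt(nrow(pirs) * p_hit * (1 - p_hit))
  expect_lt(abs(res$expected_mean - expected), sd3)
  # the observed PIRs are themselves uniform draws here -> log2 ~ 0
  # (bounded by the 3-sigma band of the overlap count)
  expect_lt(abs(res$observed - res$expected_mean), sd3)
  expect_lt(abs(res$log2_enrichment), log2(1 + sd3 / res$expected_mean))
})

test_that("TAD-boundary crossing equals a brute-force oracle", {
  boundaries <- data.table::data.table(chrom = "chrS",
    start = seq(1e6, 19e6, by = 7e5), end = seq(1e6, 19e6, by = 7e5) + 1)
  expect_equal(tad_crossing(mk_inter(5e6, 5.1e6),
    boundaries[0])$observed, 0)                  # no boundaries
  set.seed(4)
  vpc <- sample(seq(3e6, 17e6, by = 5e4), 150)
  d <- sample(c(-1, 1), 150, TRUE) * round(runif(150, 1e4, 2e6))
  inter <- mk_inter(vpc, (vpc + d) %/% 250 * 250)
  got <- tad_crossing(inter, boundaries)$observed
  bpos <- (boundaries$start + boundaries$end) / 2
  oracle <- sum(vapply(seq_len(nrow(inter)), function(i) {
    # boundary strictly between viewpoint edge and bin
    if (inter$bin_start[i] >= inter$vp_end[i])
      any(bpos > inter$vp_end[i] & bpos < inter$bin_start[i])
    else any(bpos > inter$bin_end[i] & bpos < inter$vp_start[i])
  }, logical(1)))
  expect_equal(got, oracle)
  # expected crossings come from the permutations
  perms <- permute_pirs(inter, n_perm = 10, seed = 2, chrom_sizes = sizes)
  tc <- tad_crossing(inter, boundaries, perms)
  expect_equal(tc$expected, mean(tc$per_perm))
  expect_length(tc$per_perm, 10)
})

test_that("CTCF motif orientation is towards when pointing at the promoter", {
  inter <- mk_inter(1e6, 1e6 + 50000)
  motif <- function(pos, strand) data.table::data.table(
    chrom = "chrS", start = as.integer(pos - 10), end = as.integer(pos + 9),
    strand = strand)
  # PIR right of promoter: + motif points away, - motif points towards
  away <- ctcf_orientation(inter, motif(1e6 + 50100, "+"))
  expect_equal(away$detail$orientation, "away")
  tow <- ctcf_orientation(inter, motif(1e6 + 50100, "-"))
  expect_equal(tow$detail$orientation, "towards")
  # PIR left of promoter, + motif -> towards
  inter_l <- mk_inter(1e6, 1e6 - 50250)
  tow2 <- ctcf_orientation(inter_l, motif(1e6 - 50100, "+"))
  expect_equal(tow2$detail$orientation, "towards")
  expect_error(ctcf_orientation(inter, motif(5e6, "+")), "no motifs")
  # stratification by promoter strand
  strat <- ctcf_orientation(inter, motif(1e6 + 50100, "-"),
                            promoter_strands = c("1" = "-"))
  expect_equal(strat$detail$side, "upstream")
})

test_that("symmetric motif placement gives ~50% towards", {
  set.seed(8)
  n <- 400
  vpc <- runif(n, 3e6, 17e6)
  d <- sample(c(-1, 1), n, TRUE) * round(runif(n, 1e4, 5e5))
  bin_start <- (vpc + d) %/% 250 * 250
  inter <- mk_inter(vpc, bin_start)
  motifs <- data.table::data.table(
    chrom = "chrS", start = as.integer(bin_start + 100),
    end = as.integer(bin_start + 119),
    strand = sample(c("+", "-"), n, TRUE))
  res <- ctcf_orientation(inter, motifs)
  # binomial 3 sigma around 0.5
  expect_lt(abs(res$summary$frac_towards[1] - 0.5), 3 * sqrt(0.25 / n))
})
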