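## Distance-preserving randomization of interaction other-ends, and the
## analyses built on it: TRF enrichment in PIRs, TAD-boundary crossing
## statistics, CTCF motif orientation.

#' Distance-preserving permutation of interaction other-ends
#'
#' Signed viewpoint-center to other-end-center distances are reshuffled
#' among the interactions of each chromosome; each randomized other-end is
#' placed at its viewpoint center plus a permuted signed distance, snapped
#' to the bin grid. Placements falling off the chromosome are re-drawn from
#' the original distance multiset (re-draw count in
#' `attr(x, "n_redrawn")`). Up to re-draws, the |distance| multiset of each
#' permutation equals the observed one.
#'
#' @param interactions call table with viewpoint interval columns
#'   (`chrom`, `vp_start`, `vp_end`) and other-end bin (`bin_start`,
#'   `bin_end`).
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed.
#' @param chrom_sizes named chromosome lengths.
#' @param bin_width bin width (default 250).
#' @return list of `n_perm` randomized other-end tables (`chrom`, `start`,
#'   `end`), rows parallel to `interactions`.
#' @export
permute_pirs <- function(interactions, n_perm = 100L, seed,
                         chrom_sizes, bin_width = 250L) {
  dt <- data.table::as.data.table(interactions)
  stopifnot(all(c("chrom", "vp_start", "vp_end", "bin_start", "bin_end")
                %in% names(dt)))
  vp_center <- (dt$vp_start + dt$vp_end) / 2
  dist_signed <- (dt$bin_start + dt$bin_end) / 2 - vp_center
  n_redrawn <- 0L
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(p) {
      start <- integer(nrow(dt))
      for (ch in unique(dt$chrom)) {
        idx <- which(dt$chrom == ch)
        L <- chrom_sizes[[ch]]
        d <- dist_signed[idx]
        d_perm <- if (length(idx) > 1L) sample(d) else d
        s <- as.integer(((vp_center[idx] + d_perm) %/% bin_width) * bin_width)
        bad <- which(s < 0L | (s + bin_width) > L)
        tries <- 0L
        while (length(bad) && tries < 1000L) {
          n_redrawn <<- n_redrawn + length(bad)
          d_perm[bad] <- sample(d, length(bad), replace = TRUE) *
            sample(c(-1, 1), length(bad), replace = TRUE)
          s[bad] <- as.integer(((vp_center[idx][bad] + d_perm[bad]) %/%
                                  bin_width) * bin_width)
          bad <- bad[s[bad] < 0L | (s[bad] + bin_width) > L]
          tries <- tries + 1L
        }
        s <- pmax(0L, pmin(s, as.integer(L) - as.integer(bin_width)))
        start[idx] <- s
      }
      data.table::data.table(chrom = dt$chrom, start = start,
                             end = start + as.integer(bin_width))
    })
  })
  data.table::setattr(perms, "n_redrawn", n_redrawn)
  perms
}

#' Overlap-based feature enrichment in PIRs
#'
#' Observed number of PIRs overlapping at least one feature interval,
#' against the mean over distance-preserving permutations; enrichment is
#' `log2(observed / expected_mean)`.
#'
#' @param pirs PIR interval table.
#' @param features feature interval table (already threshold-filtered).
#' @param permuted_sets list of randomized PIR tables from
#'   [permute_pirs()].
#' @param name feature label carried into the result.
#' @return one-row `data.table`: `feature`, `observed`, `expected_mean`,
#'   `expected_sd`, `log2_enrichment` (`NA` when the expectation is 0).
#' @export
feature_enrichment <- function(pirs, features, permuted_sets,
                               name = "feature") {
  fgr <- .as_gr(features)
  count_olap <- function(x)
    sum(GenomicRanges::countOverlaps(.as_gr(x), fgr) > 0)
  obs <- count_olap(pirs)
  exp_counts <- vapply(permuted_sets, count_olap, 0)
  em <- mean(exp_counts)
  data.table::data.table(
    feature = name, observed = obs, expected_mean = em,
    expected_sd = sd(exp_counts),
    log2_enrichment = if (em > 0 && obs > 0) log2(obs / em) else NA_real_)
}

#' TAD-boundary crossing of interactions
#'
#' An interaction crosses when at least one boundary point (interval
#' midpoint) lies strictly between the viewpoint edge and the other-end
#' bin. Expected crossings are the mean count over distance-preserving
#' permutations of the other-ends.
#'
#' @param interactions call table with `chrom`, `vp_start`, `vp_end`,
#'   `bin_start`, `bin_end`.
#' @param boundaries boundary interval table (`chrom`, `start`, `end`).
#' @param permuted_sets optional list of randomized other-end tables.
#' @return list with `observed`, `expected` (`NA` without permutations)
#'   and the per-permutation counts.
#' @export
tad_crossing <- function(interactions, boundaries, permuted_sets = NULL) {
  dt <- data.table::as.data.table(interactions)
  b <- data.table::as.data.table(boundaries)
  bpos <- split((b$start + b$end) / 2, b$chrom)
  count_cross <- function(bin_start, bin_end) {
    lo <- pmin(dt$vp_end, pmax(bin_end, dt$vp_start))
    crosses <- logical(nrow(dt))
    for (ch in unique(dt$chrom)) {
      pos <- bpos[[ch]]
      if (is.null(pos)) next
      idx <- which(dt$chrom == ch)
      right <- bin_start[idx] >= dt$vp_end[idx]
      span_lo <- ifelse(right, dt$vp_end[idx], bin_end[idx])
      span_hi <- ifelse(right, bin_start[idx], dt$vp_start[idx])
      crosses[idx] <- vapply(seq_along(idx), function(j)
        any(pos > span_lo[j] & pos < span_hi[j]), logical(1))
    }
    sum(crosses)
  }
  observed <- count_cross(dt$bin_start, dt$bin_end)
  per_perm <- if (!is.null(permuted_sets))
    vapply(permuted_sets, function(p) count_cross(p$start, p$end), 0)
  else numeric(0)
  list(observed = observed,
       expected = if (length(per_perm)) mean(per_perm) else NA_real_,
       per_perm = per_perm)
}

#' CTCF motif orientation relative to the interacting promoter
#'
#' Each motif overlapping an interaction's other-end bin is scored
#' `towards` when it points at the promoter on the genome axis (`+` strand
#' motif left of the promoter, or `-` strand motif right of it), otherwise
#' `away`. When promoter strands are supplied the counts are additionally
#' stratified by whether the other end lies upstream or downstream of the
#' TSS in transcription direction.
#'
#' @param interactions call table with `chrom`, `vp_start`, `vp_end`,
#'   `bin_start`, `bin_end`, `viewpoint_id`.
#' @param motifs stranded motif intervals (`chrom`, `start`, `end`,
#'   `strand`).
#' @param promoter_strands optional named vector mapping viewpoint id to
#'   promoter strand (`+`/`-`).
#' @return list: `detail` (one row per interaction-motif pair) and
#'   `summary` (counts and fractions of towards/away, overall and by side).
#' @export
ctcf_orientation <- function(interactions, motifs, promoter_strands = NULL) {
  dt <- data.table::as.data.table(interactions)
  mt <- data.table::as.data.table(motifs)
  hits <- GenomicRanges::findOverlaps(
    .as_gr(dt[, .(chrom, start = bin_start, end = bin_end)]), .as_gr(mt))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) stop("no motifs overlap the analyzed other-end bins")
  prom_pos <- (dt$vp_start + dt$vp_end)[qi] / 2
  motif_pos <- (mt$start + mt$end)[si] / 2
  towards <- (mt$strand[si] == "+" & motif_pos < prom_pos) |
             (mt$strand[si] == "-" & motif_pos > prom_pos)
  detail <- data.table::data.table(
    viewpoint_id = dt$viewpoint_id[qi],
    motif_pos = motif_pos, motif_strand = mt$strand[si],
    orientation = ifelse(towards, "towards", "away"))
  if (!is.null(promoter_strands)) {
    ps <- promoter_strands[as.character(detail$viewpoint_id)]
    # other end left of a + promoter (or right of a - promoter) is upstream
    left <- motif_pos < prom_pos
    detail$side <- ifelse((ps == "+") == left, "upstream", "downstream")
  } else detail$side <- NA_character_
  tab <- function(d, label) data.table::data.table(
    side = label,
    n_towards = sum(d$orientation == "towards"),
    n_away = sum(d$orientation == "away"),
    frac_towards = mean(d$orientation == "towards"))
  summary <- tab(detail, "all")
  if (!all(is.na(detail$side)))
    for (s in unique(detail$side))
      summary <- rbind(summary, tab(detail[detail$side == s], s))
  list(detail = detail, summary = summary)
}
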