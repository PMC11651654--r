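## Viewpoint-resolved binned contact records, the two-stage normalization
## (mononucleosomal occupancy, then viewpoint coverage), distance ranks,
## profiles, distance-decay curves and inter-replicate correlation.

#' Aggregate distal pairs into viewpoint-bin contact records
#'
#' A pair with one mate inside a viewpoint contributes one event to that
#' viewpoint and the fixed-width bin of the other mate; a pair whose two
#' mates fall in two different viewpoints contributes to both; pairs
#' touching no viewpoint are dropped. Events are aggregated per unique
#' (viewpoint, bin); zero-count combinations are never materialized.
#'
#' @param pairs deduplicated distal pair table.
#' @param viewpoints viewpoint table (`id`, `chrom`, `start`, `end`); only
#'   rows with `retained == TRUE` are used when the column is present.
#' @param bin_width other-end bin width in bp (default 250).
#' @return `data.table` of contact records: `viewpoint_id`, `chrom`,
#'   `bin_start`, `bin_end`, `raw_count`, `distance` (viewpoint edge to bin
#'   edge, bp) and `rank` (distance in bin units; 1 = directly adjacent,
#'   0 = bin overlaps the viewpoint).
#' @export
aggregate_contacts <- function(pairs, viewpoints, bin_width = 250L) {
  vp <- data.table::as.data.table(viewpoints)
  if ("retained" %in% names(vp)) vp <- vp[vp$retained]
  pairs <- data.table::as.data.table(pairs)
  vgr <- .as_gr(vp)
  pt <- function(chrom, pos) GenomicRanges::GRanges(
    chrom, IRanges::IRanges(pos + 1L, width = 1L))
  h1 <- GenomicRanges::findOverlaps(pt(pairs$chrom1, pairs$pos1), vgr)
  h2 <- GenomicRanges::findOverlaps(pt(pairs$chrom2, pairs$pos2), vgr)
  # mate1 in viewpoint -> other end is mate2, and vice versa
  ev <- data.table::rbindlist(list(
    data.table::data.table(
      vp_row = S4Vectors::subjectHits(h1),
      chrom = pairs$chrom2[S4Vectors::queryHits(h1)],
      pos = pairs$pos2[S4Vectors::queryHits(h1)]),
    data.table::data.table(
      vp_row = S4Vectors::subjectHits(h2),
      chrom = pairs$chrom1[S4Vectors::queryHits(h2)],
      pos = pairs$pos1[S4Vectors::queryHits(h2)])
  ))
  if (!nrow(ev)) return(data.table::data.table(
    viewpoint_id = integer(), chrom = character(), bin_start = integer(),
    bin_end = integer(), raw_count = integer(), distance = integer(),
    rank = integer()))
  ev[, `:=`(bin_start = as.integer(pos %/% bin_width) * bin_width)]
  rec <- ev[, .(raw_count = .N), by = .(vp_row, chrom, bin_start)]
  rec[, `:=`(
    viewpoint_id = vp$id[vp_row],
    bin_end = bin_start + as.integer(bin_width),
    vp_chrom = vp$chrom[vp_row],
    vp_start = vp$start[vp_row],
    vp_end = vp$end[vp_row])]
  rec[, c("distance", "rank") := {
    gap <- rep(NA_integer_, .N)
    cis <- chrom == vp_chrom
    g <- pmax(bin_start - vp_end, vp_start - (bin_start + as.integer(bin_width)))
    gap[cis] <- pmax(g[cis], -1L)      # -1 marks overlap
    r <- ifelse(is.na(gap), NA_integer_,
                ifelse(gap < 0L, 0L, 1L + gap %/% as.integer(bin_width)))
    .(as.integer(pmax(gap, 0L)), as.integer(r))
  }]
  out <- rec[, .(viewpoint_id, chrom, bin_start, bin_end, raw_count,
                 distance, rank)]
  data.table::setorder(out, viewpoint_id, chrom, bin_start)
  out[]
}

#' Distance rank of a viewpoint-bin gap
#'
#' @param gap bp between the nearest viewpoint edge and the nearest bin
#'   edge (0 for directly adjacent bins); negative values denote overlap.
#' @param bin_width bin width (default 250).
#' @return integer ranks; 0 for overlapping bins.
#' @export
distance_rank <- function(gap, bin_width = 250L) {
  ifelse(gap < 0, 0L, 1L + as.integer(gap) %/% as.integer(bin_width))
}

#' Two-stage normalization of contact records
#'
#' Records farther than `max_distance` from their viewpoint are removed.
#' `occ_norm` divides the raw count by the mean mononucleosomal occupancy
#' of the viewpoint and the other-end bin; `vp_norm` divides `occ_norm` by
#' the viewpoint coverage (the sum of the viewpoint's surviving `occ_norm`
#' values), so per-viewpoint `vp_norm` sums to 1. Records whose mean
#' occupancy is zero are dropped; the count is in
#' `attr(x, "dropped_zero_occ")`.
#'
#' @param records contact records from [aggregate_contacts()].
#' @param viewpoints viewpoint table with `mono_occupancy`.
#' @param mono_track mononucleosomal coverage `RleList` (for bin occupancy).
#' @param max_distance distance window in bp (default 2.5e6).
#' @return normalized `data.table` with `occ_norm` and `vp_norm` columns.
#' @export
normalize_contacts <- function(records, viewpoints, mono_track,
                               max_distance = 2.5e6) {
  rec <- data.table::as.data.table(records)
  vp <- data.table::as.data.table(viewpoints)
  rec <- rec[distance <= max_distance]
  occ_vp <- vp$mono_occupancy[match(rec$viewpoint_id, vp$id)]
  occ_bin <- region_occupancy(mono_track, rec[, .(chrom, start = bin_start,
                                                  end = bin_end)])
  mean_occ <- (occ_vp + occ_bin) / 2
  drop <- mean_occ <= 0
  n_drop <- sum(drop)
  if (n_drop) message(n_drop, " record(s) with zero mean occupancy dropped")
  rec <- rec[!drop]
  rec[, occ_norm := raw_count / mean_occ[!drop]]
  rec[, vp_norm := occ_norm / sum(occ_norm), by = viewpoint_id]
  data.table::setattr(rec, "dropped_zero_occ", n_drop)
  rec[]
}

#' Binned interaction profile over a region
#'
#' Per-bin sums of other-end events across all viewpoints (merged profile)
#' or for a single viewpoint.
#'
#' @param records contact records.
#' @param region list or data.frame row with `chrom`, `start`, `end`.
#' @param bin_width bin width (default 250); record bins must align.
#' @param viewpoint optional viewpoint id filter.
#' @param value column to sum (default `"raw_count"`).
#' @return `data.table` profile (`chrom`, `start`, `end`, `value`) tiling
#'   the region, with attribute `kind`.
#' @export
build_profile <- function(records, region, bin_width = 250L,
                          viewpoint = NULL, value = "raw_count") {
  rec <- data.table::as.data.table(records)
  if (!is.null(viewpoint)) rec <- rec[viewpoint_id %in% viewpoint]
  bins <- make_bins(region$chrom, region$start, region$end, bin_width)
  rec <- rec[chrom == region$chrom & bin_start >= bins$start[1] &
               bin_start < region$end]
  agg <- rec[, .(value = sum(.SD[[1]])), by = .(start = bin_start),
             .SDcols = value]
  bins[, value := 0]
  bins[agg, value := i.value, on = "start"]
  data.table::setattr(bins, "kind",
                      if (is.null(viewpoint)) "merged" else "viewpoint-specific")
  bins[]
}

#' Distance-decay curve
#'
#' Aggregated signal in log10-equal distance bins (default 30 bins between
#' 10^3.5 = 3,162 bp and 10^6.5 bp). Records at distances outside the range
#' are ignored.
#'
#' @param records contact records with a positive `distance`.
#' @param n_bins number of distance bins (default 30).
#' @param log10_min,log10_max log10 bounds (defaults 3.5 and 6.5).
#' @param value column to sum (default `"raw_count"`).
#' @return `data.table` with `bin`, `d_low`, `d_high`, `signal`.
#' @export
distance_decay <- function(records, n_bins = 30L, log10_min = 3.5,
                           log10_max = 6.5, value = "raw_count") {
  rec <- data.table::as.data.table(records)
  breaks <- 10^seq(log10_min, log10_max, length.out = n_bins + 1L)
  idx <- findInterval(rec$distance, breaks, rightmost.closed = TRUE)
  ok <- idx >= 1L & idx <= n_bins & rec$distance > 0
  sig <- numeric(n_bins)
  if (any(ok)) {
    agg <- data.table::data.table(bin = idx[ok], v = rec[[value]][ok])[
      , .(s = sum(v)), by = bin]
    sig[agg$bin] <- agg$s
  }
  data.table::data.table(bin = seq_len(n_bins),
                         d_low = breaks[-(n_bins + 1L)],
                         d_high = breaks[-1L], signal = sig)
}

#' Pearson correlation of two binned profiles
#'
#' Bins overlapping `exclude` intervals are removed; when
#' `require_nonzero` is set, bins with a zero value in either profile are
#' removed as well (the merged-profile inter-replicate filter).
#'
#' @param a,b profiles with identical binning (`chrom`, `start`, `end`,
#'   `value`).
#' @param exclude optional interval table to mask (e.g. viewpoints).
#' @param require_nonzero drop bins that are zero in either profile
#'   (default TRUE).
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(a, b, exclude = NULL, require_nonzero = TRUE) {
  a <- data.table::as.data.table(a); b <- data.table::as.data.table(b)
  if (nrow(a) != nrow(b) || !all(a$start == b$start & a$chrom == b$chrom))
    stop("profiles must share identical binning")
  keep <- rep(TRUE, nrow(a))
  if (!is.null(exclude) && nrow(exclude)) {
    hits <- GenomicRanges::findOverlaps(.as_gr(a), .as_gr(exclude))
    keep[unique(S4Vectors::queryHits(hits))] <- FALSE
  }
  if (require_nonzero) keep <- keep & a$value > 0 & b$value > 0
  if (sum(keep) < 2L) stop("fewer than 2 usable bins after filtering")
  stats::cor(a$value[keep], b$value[keep])
}
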