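## Consensus capture viewpoints from replicate mononucleosomal peak sets,
## and per-region mononucleosomal occupancy used for signal normalization.

#' Consensus peaks across replicates
#'
#' Maximal regions covered by peaks from at least `min_reps` distinct
#' replicates; consensus regions separated by less than `merge_gap` bp
#' (end-to-start) are then merged.
#'
#' @param peaksets list of peak tables (`chrom`, `start`, `end`, ...), one
#'   per replicate.
#' @param min_reps minimum number of replicates covering a base (default 3).
#' @param merge_gap merge consensus regions closer than this many bp
#'   (default 1000; strict `<`).
#' @return `data.table` of consensus intervals.
#' @export
consensus_peaks <- function(peaksets, min_reps = 3L, merge_gap = 1000L) {
  if (length(peaksets) < min_reps)
    stop("need at least `min_reps` peak sets")
  grl <- lapply(peaksets, function(p) {
    if (!nrow(p)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(.as_gr(p))    # presence/absence per replicate
  })
  all_gr <- do.call(c, grl)
  if (!length(all_gr)) return(data.table::data.table(
    chrom = character(), start = integer(), end = integer()))
  cov <- GenomicRanges::coverage(all_gr)
  cons <- GenomicRanges::GRanges(IRanges::slice(cov, lower = min_reps,
                                                rangesOnly = TRUE))
  # gap >= merge_gap stays split; gap < merge_gap merges
  merged <- GenomicRanges::reduce(cons, min.gapwidth = merge_gap)
  out <- .gr_as_dt(merged)
  data.table::setorder(out, chrom, start)
  out[]
}

#' Per-base coverage track from fragment intervals
#'
#' @param fragments interval table (`chrom`, `start`, `end`).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return an `RleList` of per-base depth.
#' @export
coverage_track <- function(fragments, chrom_sizes) {
  gr <- if (is.null(fragments) || !nrow(fragments))
    GenomicRanges::GRanges(seqlengths = chrom_sizes)
  else .as_gr(fragments, chrom_sizes)
  GenomicRanges::coverage(gr)
}

#' Mean per-base depth over regions
#'
#' Total aligned bases in each region divided by region length.
#'
#' @param track coverage `RleList` from [coverage_track()].
#' @param regions interval table (`chrom`, `start`, `end`).
#' @return numeric vector of mean depths, one per region.
#' @export
region_occupancy <- function(track, regions) {
  regions <- data.table::as.data.table(regions)
  if (!nrow(regions)) return(numeric(0))
  if (any(regions$end <= regions$start)) stop("empty region")
  .check_chroms(regions$chrom, setNames(lengths(track), names(track)))
  out <- numeric(nrow(regions))
  for (ch in unique(regions$chrom)) {
    idx <- which(regions$chrom == ch)
    v <- IRanges::Views(track[[ch]],
                        start = regions$start[idx] + 1L,
                        end = regions$end[idx])
    out[idx] <- IRanges::viewSums(v) / (regions$end[idx] - regions$start[idx])
  }
  out
}

#' Build viewpoint table from consensus peaks
#'
#' Attaches an id, mononucleosomal occupancy and raw total distal-pair
#' coverage (pairs from all replicates with at least one mate inside the
#' viewpoint) to each consensus region, then flags retained viewpoints.
#'
#' @param consensus consensus peak table from [consensus_peaks()].
#' @param mono_track mononucleosomal coverage `RleList`.
#' @param distal_pairs distal pair table pooled over replicates (may be
#'   `NULL`; coverage is then 0).
#' @param min_coverage retention threshold: raw total coverage must exceed
#'   this (default 1000, strict `>`).
#' @return `data.table` with `id`, interval, `mono_occupancy`,
#'   `raw_total_coverage`, `retained`.
#' @export
build_viewpoints <- function(consensus, mono_track, distal_pairs = NULL,
                             min_coverage = 1000L) {
  vp <- data.table::as.data.table(consensus)[, .(chrom, start, end)]
  data.table::setorder(vp, chrom, start)
  vp[, `:=`(id = seq_len(.N))]
  vp$mono_occupancy <- if (is.null(mono_track)) NA_real_
                       else region_occupancy(mono_track, vp)
  vp$raw_total_coverage <- if (is.null(distal_pairs)) 0L
                           else .viewpoint_pair_counts(vp, distal_pairs)
  filter_viewpoints(vp, min_coverage)
}

## number of pairs with >=1 mate position inside each viewpoint
.viewpoint_pair_counts <- function(vp, pairs) {
  pairs <- data.table::as.data.table(pairs)
  vgr <- .as_gr(vp)
  p1 <- GenomicRanges::GRanges(pairs$chrom1,
          IRanges::IRanges(pairs$pos1 + 1L, width = 1L))
  p2 <- GenomicRanges::GRanges(pairs$chrom2,
          IRanges::IRanges(pairs$pos2 + 1L, width = 1L))
  h1 <- GenomicRanges::findOverlaps(p1, vgr)
  h2 <- GenomicRanges::findOverlaps(p2, vgr)
  hits <- unique(data.table::data.table(
    pair = c(S4Vectors::queryHits(h1), S4Vectors::queryHits(h2)),
    vp = c(S4Vectors::subjectHits(h1), S4Vectors::subjectHits(h2))))
  counts <- hits[, .N, by = vp]
  out <- integer(nrow(vp))
  out[counts$vp] <- counts$N
  out
}

#' Flag viewpoints passing the raw-coverage filter
#'
#' @param viewpoints viewpoint table with `raw_total_coverage`.
#' @param min_coverage strict threshold (retained iff coverage >
#'   `min_coverage`; default 1000).
#' @return the table, order preserved, with `retained` updated.
#' @export
filter_viewpoints <- function(viewpoints, min_coverage = 1000L) {
  vp <- data.table::as.data.table(viewpoints)
  vp$retained <- vp$raw_total_coverage > min_coverage
  vp[]
}

#' Fixed-threshold mononucleosomal peak caller (synthetic-data path)
#'
#' A deliberately simple caller used only to turn simulated mononucleosomal
#' coverage into replicate peak files: regions where depth exceeds
#' `k` times the genome-mean depth, wider than `min_width` bp. Real
#' experiments provide externally called narrowPeak files instead.
#'
#' @param track coverage `RleList`.
#' @param k depth multiplier over the genome mean (default 4).
#' @param min_width minimum peak width in bp (default 147).
#' @return `data.table` of peak intervals.
#' @export
call_mono_peaks <- function(track, k = 4, min_width = 147L) {
  mean_depth <- sum(vapply(track, function(r) sum(as.numeric(r)), 0)) /
    sum(lengths(track))
  thr <- max(k * mean_depth, 1e-9)
  peaks <- GenomicRanges::GRanges(IRanges::slice(track, lower = thr,
                                                 rangesOnly = TRUE))
  peaks <- peaks[GenomicRanges::width(peaks) >= min_width]
  .gr_as_dt(peaks)
}
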