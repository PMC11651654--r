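## Benchmarking interaction calls against CRISPRi-verified enhancer-promoter
## pairs: anchored overlap with padded PIRs, confusion statistics with Wald
## confidence intervals, signal/background enrichment at distal sites, and a
## genomic-distance baseline predictor.

#' Label element-gene pairs by overlap with interaction calls
#'
#' A pair is `interacting` when some call shares the pair's promoter
#' viewpoint and its other-end bin, extended by `pir_pad` bp on both sides,
#' overlaps the element by at least 1 bp. Pairs whose promoter matches no
#' viewpoint (`viewpoint_id` NA) are excluded; the count is in
#' `attr(x, "n_excluded")`.
#'
#' @param pairs element-gene table (`chrom`, `start`, `end`,
#'   `viewpoint_id`, `label` in `{verified-regulatory, non-regulatory}`).
#' @param calls interaction call table (`viewpoint_id`, `chrom`,
#'   `bin_start`, `bin_end`).
#' @param pir_pad other-end padding in bp (default 500; use 2500 for
#'   loop-anchor style calls).
#' @return pairs with a logical `interacting` column.
#' @export
overlap_calls <- function(pairs, calls, pir_pad = 500L) {
  pairs <- data.table::as.data.table(pairs)
  calls <- data.table::as.data.table(calls)
  excluded <- is.na(pairs$viewpoint_id)
  out <- pairs[!excluded]
  padded <- calls[, .(viewpoint_id, chrom,
                      start = pmax(0L, bin_start - as.integer(pir_pad)),
                      end = bin_end + as.integer(pir_pad))]
  out$interacting <- FALSE
  if (nrow(padded) && nrow(out)) {
    hits <- GenomicRanges::findOverlaps(.as_gr(out), .as_gr(padded))
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    same_vp <- out$viewpoint_id[qi] == padded$viewpoint_id[si]
    out$interacting[unique(qi[same_vp])] <- TRUE
  }
  data.table::setattr(out, "n_excluded", sum(excluded))
  out[]
}

#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' `[0, 1]`.
#'
#' @param k successes.
#' @param n trials (>= 1).
#' @param z normal quantile (default 1.96 for 95%).
#' @param percent report bounds as percentages rounded half-up to one
#'   decimal (default TRUE).
#' @return named vector `c(low, high)`.
#' @export
wald_ci <- function(k, n, z = 1.96, percent = TRUE) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  p <- k / n
  half <- z * sqrt(p * (1 - p) / n)
  ci <- c(low = max(0, p - half), high = min(1, p + half))
  if (percent) round_half_up(100 * ci, 1) else ci
}

#' Confusion statistics for labeled element-gene pairs
#'
#' Verified pairs with an interaction are true positives; non-regulatory
#' pairs with an interaction are false positives. Recall, precision and
#' false positive rate are reported as percentages (half-up, one decimal)
#' with 95% Wald confidence intervals.
#'
#' @param labeled labeled pair table from [overlap_calls()], or `NULL`
#'   when counts are given directly.
#' @param tp,fn,fp,tn confusion counts, used when `labeled` is `NULL`.
#' @param z normal quantile for the intervals (default 1.96).
#' @return object of class `confusion_stats`: counts, rates (fractions),
#'   `*_pct` percentages and `*_ci` percentage intervals.
#' @export
confusion_stats <- function(labeled = NULL, tp = NULL, fn = NULL,
                            fp = NULL, tn = NULL, z = 1.96) {
  if (!is.null(labeled)) {
    labeled <- data.table::as.data.table(labeled)
    stopifnot(all(labeled$label %in% c("verified-regulatory",
                                       "non-regulatory")))
    pos <- labeled$label == "verified-regulatory"
    tp <- sum(pos & labeled$interacting)
    fn <- sum(pos & !labeled$interacting)
    fp <- sum(!pos & labeled$interacting)
    tn <- sum(!pos & !labeled$interacting)
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- rate(tp, tp + fn)
  precision <- rate(tp, tp + fp)
  fpr <- rate(fp, fp + tn)
  ci <- function(num, den) if (den > 0) wald_ci(num, den, z) else
    c(low = NA_real_, high = NA_real_)
  structure(list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    recall = recall, precision = precision, fpr = fpr,
    recall_pct = round_half_up(100 * recall, 1),
    precision_pct = round_half_up(100 * precision, 1),
    fpr_pct = round_half_up(100 * fpr, 1),
    recall_ci = ci(tp, tp + fn),
    precision_ci = ci(tp, tp + fp),
    fpr_ci = ci(fp, fp + tn)
  ), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fn=%d fp=%d tn=%d\n", x$tp, x$fn, x$fp, x$tn))
  line <- function(nm, pct, ci) cat(sprintf(
    "  %-9s %5.1f%%  (95%% CI [%.1f%%; %.1f%%])\n", nm, pct, ci[1], ci[2]))
  line("recall", x$recall_pct, x$recall_ci)
  line("precision", x$precision_pct, x$precision_ci)
  line("FPR", x$fpr_pct, x$fpr_ci)
  invisible(x)
}

#' Signal and background enrichment around distal sites
#'
#' For each site midpoint m, samples the profile in the two central bins
#' (m - 125 and m + 125 for 250-bp bins), the two bins 1 kb away and the
#' two bins 5 kb away (one per side), averaging the two bins per set. The
#' center enrichment is stat(center) / stat(5 kb background); the
#' resolution ratio is stat(1 kb) / stat(5 kb).
#'
#' @param profile binned profile (`chrom`, `start`, `end`, `value`).
#' @param sites site interval table (midpoints are used).
#' @param stat `"median"` (default) or `"mean"`.
#' @param bin_width profile bin width (default 250).
#' @return list: `center_ratio`, `resolution_ratio`, and the per-site
#'   matrix of (center, bg1kb, bg5kb) values.
#' @export
site_enrichment_profile <- function(profile, sites, stat = c("median", "mean"),
                                    bin_width = 250L) {
  stat <- match.arg(stat)
  sfun <- if (stat == "median") median else mean
  sites <- data.table::as.data.table(sites)
  if (!nrow(sites)) stop("empty site list")
  prof <- data.table::as.data.table(profile)
  lookup <- function(chrom, pos) {
    key <- data.table::data.table(chrom = chrom,
                                  start = as.integer(pos %/% bin_width) * bin_width)
    prof[key, on = c("chrom", "start")]$value
  }
  mid <- (sites$start + sites$end) / 2
  two_bin <- function(offset) {
    v1 <- lookup(sites$chrom, mid - offset)
    v2 <- lookup(sites$chrom, mid + offset)
    rowMeans(cbind(v1, v2), na.rm = TRUE)
  }
  m <- cbind(center = two_bin(bin_width / 2),
             bg1kb = two_bin(1000), bg5kb = two_bin(5000))
  bg5 <- sfun(m[, "bg5kb"], na.rm = TRUE)
  ratio <- function(x) if (is.finite(bg5) && bg5 > 0)
    sfun(x, na.rm = TRUE) / bg5 else NA_real_
  if (!is.finite(bg5) || bg5 <= 0) message("zero 5 kb background statistic")
  list(center_ratio = ratio(m[, "center"]),
       resolution_ratio = ratio(m[, "bg1kb"]), matrix = m)
}

#' Distance-threshold baseline predictor
#'
#' Predicts "regulatory" when the element-promoter distance is at most the
#' threshold; one ROC/PR point per threshold.
#'
#' @param pairs labeled pair table with a `distance` column.
#' @param thresholds distance thresholds in bp.
#' @return `data.table` with `threshold`, `recall`, `precision`, `fpr`.
#' @export
distance_baseline <- function(pairs, thresholds) {
  pairs <- data.table::as.data.table(pairs)
  pos <- pairs$label == "verified-regulatory"
  res <- lapply(thresholds, function(thr) {
    pred <- pairs$distance <= thr
    data.table::data.table(
      threshold = thr,
      recall = sum(pos & pred) / sum(pos),
      precision = if (any(pred)) sum(pos & pred) / sum(pred) else NA_real_,
      fpr = sum(!pos & pred) / sum(!pos))
  })
  data.table::rbindlist(res)
}
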