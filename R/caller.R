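## Interaction calling: per-distance-rank Weibull background fitted on
## normalized signal, upper-tail p-values, count thresholds, replicate
## reproducibility and P-P / P-PIR classification.

#' Fit a two-parameter Weibull background for one distance rank
#'
#' Maximum-likelihood fit (location 0) on the positive normalized signal
#' values observed at one rank. The shape parameter is found by profile
#' likelihood: for fixed shape k the MLE scale satisfies
#' `scale^k = mean(x^k)`, leaving a one-dimensional maximization solved by
#' golden-section search bracketed around a method-of-moments start.
#'
#' @param values positive normalized signal values at this rank.
#' @param min_obs minimum observations for a usable fit (default 50).
#' @param rank rank label carried in the result.
#' @return object of class `rank_background`: list with `rank`, `shape`,
#'   `scale`, `n_obs`, `fit_ok`.
#' @export
fit_rank_background <- function(values, min_obs = 50L, rank = NA_integer_) {
  if (any(values <= 0)) stop("background values must be positive")
  n <- length(values)
  fail <- function() structure(list(rank = rank, shape = NA_real_,
    scale = NA_real_, n_obs = n, fit_ok = FALSE), class = "rank_background")
  if (n < min_obs) return(fail())
  lx <- log(values)
  mlx <- mean(lx)
  # profile log-likelihood in shape k, scale profiled out
  prof <- function(k) {
    # log mean(x^k), computed stably
    z <- k * lx; m <- max(z)
    lmean <- m + log(mean(exp(z - m)))
    n * log(k) - n * lmean + (k - 1) * n * mlx - n
  }
  # method-of-moments start from the CV, with a wide bracket
  cv <- sd(values) / mean(values)
  k0 <- if (!is.finite(cv) || cv <= 0) 1 else max(0.05, min(20, cv^-1.086))
  opt <- tryCatch(
    optimize(prof, lower = k0 / 50, upper = k0 * 50,
             maximum = TRUE, tol = 1e-8),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$maximum)) return(fail())
  k <- opt$maximum
  z <- k * lx; m <- max(z)
  scale <- exp((m + log(mean(exp(z - m)))) / k)
  if (!is.finite(scale) || scale <= 0 || k <= 0) return(fail())
  structure(list(rank = rank, shape = k, scale = scale, n_obs = n,
                 fit_ok = TRUE), class = "rank_background")
}

#' Upper-tail Weibull p-value
#'
#' Survival probability `S(x) = exp(-(x/scale)^shape)` under a fitted rank
#' background.
#'
#' @param x non-negative observed value(s).
#' @param bg a `rank_background` with `fit_ok = TRUE`, or shape/scale pair.
#' @return p-value(s) in `[0, 1]`.
#' @export
weibull_pvalue <- function(x, bg) {
  if (any(x < 0)) stop("x must be non-negative")
  if (inherits(bg, "rank_background")) {
    if (!bg$fit_ok) stop("background fit not usable")
    exp(-(x / bg$scale)^bg$shape)
  } else exp(-(x / bg[["scale"]])^bg[["shape"]])
}

#' Fit backgrounds for all ranks in the calling window
#'
#' One Weibull fit per distance rank between `near_rank` and `far_rank` on
#' the normalized signal of all records at that rank. Ranks with too few
#' observations (or failed fits) are marked `fit_ok = FALSE` and borrow the
#' nearest usable rank's background at calling time.
#'
#' @param records normalized contact records.
#' @param near_rank,far_rank calling window in ranks (defaults 20, 4000).
#' @param min_obs minimum observations per rank (default 50).
#' @param value signal column to model (default `"vp_norm"`).
#' @return `data.table` (class `rank_backgrounds`) with one row per rank
#'   holding `shape`, `scale`, `n_obs`, `fit_ok`.
#' @export
fit_backgrounds <- function(records, near_rank = 20L, far_rank = 4000L,
                            min_obs = 50L, value = "vp_norm") {
  rec <- data.table::as.data.table(records)
  rec <- rec[rank >= near_rank & rank <= far_rank]
  fits <- rec[, {
    bg <- fit_rank_background(.SD[[1]], min_obs = min_obs, rank = .BY$rank)
    .(shape = bg$shape, scale = bg$scale, n_obs = bg$n_obs, fit_ok = bg$fit_ok)
  }, by = rank, .SDcols = value]
  data.table::setorder(fits, rank)
  data.table::setattr(fits, "class",
                      c("rank_backgrounds", class(fits)))
  fits
}

## nearest fit_ok rank for each requested rank (ties -> lower rank)
.nearest_background <- function(backgrounds, ranks) {
  ok <- backgrounds[backgrounds$fit_ok == TRUE]
  if (!nrow(ok)) stop("no usable background fits")
  idx <- vapply(ranks, function(r) which.min(abs(ok$rank - r)), 0L)
  ok[idx]
}

#' Call significant viewpoint-bin interactions
#'
#' Within the rank window, a record is called when its upper-tail Weibull
#' p-value is below `alpha` and its raw count passes the count rule
#' (strictly greater than `min_reads` by default). Beyond `far_rank`,
#' records are called on the count rule alone (no p-value). Ranks below
#' `near_rank`, and bins overlapping their own viewpoint (rank 0), are
#' never called. Records at ranks without a usable fit are evaluated
#' against the nearest usable rank's background; the number of such
#' borrowings is in `attr(x, "n_borrowed")`.
#'
#' @param records normalized contact records.
#' @param backgrounds `rank_backgrounds` from [fit_backgrounds()].
#' @param alpha p-value threshold (default 0.01, strict `<`).
#' @param min_reads raw-count threshold (default 3).
#' @param count_inclusive if `FALSE` (default) require `raw_count >
#'   min_reads`; if `TRUE` require `raw_count >= min_reads`.
#' @param near_rank,far_rank calling window (defaults 20, 4000).
#' @param value signal column scored against the background.
#' @return `data.table` of interaction calls (`viewpoint_id`, bin,
#'   `raw_count`, `normalized`, `rank`, `p_value`; `p_value` is `NA` for
#'   far-rank count-only calls).
#' @export
call_interactions <- function(records, backgrounds, alpha = 0.01,
                              min_reads = 3L, count_inclusive = FALSE,
                              near_rank = 20L, far_rank = 4000L,
                              value = "vp_norm") {
  rec <- data.table::as.data.table(records)
  count_ok <- if (count_inclusive) rec$raw_count >= min_reads
              else rec$raw_count > min_reads
  in_window <- rec$rank >= near_rank & rec$rank <= far_rank
  beyond <- rec$rank > far_rank

  pv <- rep(NA_real_, nrow(rec))
  n_borrowed <- 0L
  if (any(in_window)) {
    idx <- which(in_window)
    bgs <- .nearest_background(backgrounds, rec$rank[idx])
    n_borrowed <- sum(bgs$rank != rec$rank[idx])
    pv[idx] <- exp(-(rec[[value]][idx] / bgs$scale)^bgs$shape)
  }
  called <- (in_window & !is.na(pv) & pv < alpha & count_ok) |
            (beyond & count_ok)
  out <- rec[called, .(viewpoint_id, chrom, bin_start, bin_end, raw_count,
                       normalized = .SD[[1]], rank), .SDcols = value]
  out$p_value <- pv[called]
  data.table::setattr(out, "n_borrowed", n_borrowed)
  out[]
}

#' Interaction calling on aggregated (summed-replicate) signal
#'
#' Same procedure as [call_interactions()] with the raw-read criterion
#' raised to a minimum of `min_reads` reads (inclusive; default 6).
#'
#' @inheritParams call_interactions
#' @param min_reads minimal raw reads (inclusive; default 6).
#' @return `data.table` of interaction calls.
#' @export
call_aggregate <- function(records, backgrounds, alpha = 0.01,
                           min_reads = 6L, near_rank = 20L,
                           far_rank = 4000L, value = "vp_norm") {
  call_interactions(records, backgrounds, alpha = alpha,
                    min_reads = min_reads, count_inclusive = TRUE,
                    near_rank = near_rank, far_rank = far_rank, value = value)
}

#' Inter-replicate reproducibility of interaction calls
#'
#' Two calls correspond when their viewpoints are identical and their
#' other-end bin centers lie within `tolerance` bp. For each replicate,
#' reports the fraction of its calls with a correspondent in at least one
#' other replicate.
#'
#' @param call_sets list (length >= 2) of per-replicate call tables.
#' @param tolerance other-end center tolerance in bp (default 1000).
#' @return `data.table` with `replicate`, `n_calls`, `fraction_reproduced`.
#' @export
replicate_reproducibility <- function(call_sets, tolerance = 1000L) {
  if (length(call_sets) < 2L) stop("need at least two replicates")
  centers <- lapply(call_sets, function(x) {
    dt <- data.table::as.data.table(x)
    dt[, .(viewpoint_id, center = (bin_start + bin_end) / 2)]
  })
  res <- lapply(seq_along(centers), function(i) {
    mine <- centers[[i]]
    if (!nrow(mine)) return(data.table::data.table(
      replicate = i, n_calls = 0L, fraction_reproduced = NA_real_))
    others <- data.table::rbindlist(centers[-i])
    hit <- vapply(seq_len(nrow(mine)), function(j) {
      any(others$viewpoint_id == mine$viewpoint_id[j] &
          abs(others$center - mine$center[j]) <= tolerance)
    }, logical(1))
    data.table::data.table(replicate = i, n_calls = nrow(mine),
                           fraction_reproduced = mean(hit))
  })
  data.table::rbindlist(res)
}

#' Classify calls as promoter-promoter or promoter-PIR
#'
#' A call is `P-P` when its other-end bin overlaps any viewpoint interval,
#' otherwise `P-PIR`.
#'
#' @param calls interaction call table.
#' @param viewpoints viewpoint table.
#' @return calls with a `klass` column.
#' @export
classify_calls <- function(calls, viewpoints) {
  calls <- data.table::as.data.table(calls)
  vp <- data.table::as.data.table(viewpoints)
  if (!nrow(calls)) { calls$klass <- character(0); return(calls) }
  hits <- GenomicRanges::findOverlaps(
    .as_gr(calls[, .(chrom, start = bin_start, end = bin_end)]), .as_gr(vp))
  calls$klass <- "P-PIR"
  calls$klass[unique(S4Vectors::queryHits(hits))] <- "P-P"
  calls[]
}

#' Deduplicated set of promoter-interacting regions (PIRs)
#'
#' Unique other-end bins of `P-PIR` calls.
#'
#' @param calls classified call table (see [classify_calls()]).
#' @return `data.table` of unique PIR bins.
#' @export
pir_set <- function(calls) {
  calls <- data.table::as.data.table(calls)
  unique(calls[klass == "P-PIR",
               .(chrom, start = bin_start, end = bin_end)])
}
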