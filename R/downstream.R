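## Downstream characterization of promoter-interacting regulatory elements:
## binary TRF-binding matrices, Ward clustering with enhancer-enrichment
## annotation, greedy forward feature selection with random-forest models
## of contact strength, and small shared utilities (IQR outlier filter,
## coverage correlation).

#' Binary TRF-binding matrix over regulatory elements
#'
#' Cell (i, j) is 1 when element i overlaps at least one peak of factor j.
#' Factors are retained when bound to more than `min_bound` elements and,
#' if an enrichment table is supplied, when their PIR enrichment exceeds
#' `min_enrich`.
#'
#' @param dhs element interval table (`chrom`, `start`, `end`); rownames of
#'   the result are `dhs$name` when present, else row indices.
#' @param trf_sets named list of peak tables, already signal-filtered.
#' @param enrichment optional enrichment table (`feature`,
#'   `log2_enrichment`) from [feature_enrichment()].
#' @param min_bound keep factors bound to more than this many elements
#'   (default 1000, strict `>`).
#' @param min_enrich keep factors with enrichment above this (default 2,
#'   strict `>`).
#' @return binary integer matrix (elements x factors).
#' @export
build_binding_matrix <- function(dhs, trf_sets, enrichment = NULL,
                                 min_bound = 1000L, min_enrich = 2) {
  dhs <- data.table::as.data.table(dhs)
  dgr <- .as_gr(dhs)
  mat <- vapply(trf_sets, function(p)
    as.integer(GenomicRanges::countOverlaps(dgr, .as_gr(p)) > 0),
    integer(nrow(dhs)))
  if (nrow(dhs) == 1L) mat <- matrix(mat, nrow = 1L,
                                     dimnames = list(NULL, names(trf_sets)))
  rownames(mat) <- if ("name" %in% names(dhs)) dhs$name
                   else as.character(seq_len(nrow(dhs)))
  keep <- colSums(mat) > min_bound
  if (!is.null(enrichment)) {
    enr <- setNames(enrichment$log2_enrichment, enrichment$feature)
    keep <- keep & !is.na(enr[colnames(mat)]) & enr[colnames(mat)] > min_enrich
  }
  mat[, keep, drop = FALSE]
}

#' Ward clustering of elements by binding profile
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances between binary binding rows, cut at `k` clusters.
#' Also reports, per cluster, the `top_n` factors bound to the greatest
#' number of elements, and the union of these lists.
#'
#' @param matrix binary binding matrix from [build_binding_matrix()].
#' @param k number of clusters (default 4).
#' @param top_n factors summarized per cluster (default 20).
#' @return list: `assignment` (`data.table` of element id and cluster),
#'   `top_trfs` (per-cluster character vectors), `top_union`, and the
#'   `hclust` tree.
#' @export
cluster_dhs <- function(matrix, k = 4L, top_n = 20L) {
  if (k > nrow(matrix)) stop("k exceeds the number of rows")
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  assignment <- data.table::data.table(dhs_id = rownames(matrix),
                                       cluster = as.integer(cl))
  top_trfs <- lapply(seq_len(k), function(c) {
    sub <- matrix[cl == c, , drop = FALSE]
    counts <- colSums(sub)
    names(sort(counts, decreasing = TRUE))[seq_len(min(top_n, ncol(matrix)))]
  })
  names(top_trfs) <- paste0("cluster", seq_len(k))
  list(assignment = assignment, top_trfs = top_trfs,
       top_union = unique(unlist(top_trfs)), hclust = hc)
}

#' One-sided binomial enhancer enrichment per cluster
#'
#' Verified enhancers are mapped to the clustered elements they overlap
#' (enhancers overlapping none are dropped and counted). For cluster c with
#' x of the n enhancer-overlapping elements and null proportion
#' p0 = |c| / total elements, the p-value is `P(X >= x)` under
#' Binomial(n, p0).
#'
#' @param assignment cluster assignment table (`dhs_id`, `cluster`).
#' @param dhs element intervals in assignment order (`chrom`, `start`,
#'   `end`; `name` matching `dhs_id` when present).
#' @param enhancers verified-element interval table.
#' @return `data.table` per cluster: size, `x`, `n`, `p0`, `p_value`
#'   (empty cluster -> 1); unmapped enhancer count in
#'   `attr(x, "n_unmapped")`.
#' @export
cluster_enhancer_test <- function(assignment, dhs, enhancers) {
  assignment <- data.table::as.data.table(assignment)
  dhs <- data.table::as.data.table(dhs)
  hits <- GenomicRanges::countOverlaps(.as_gr(dhs), .as_gr(enhancers))
  enh_dhs <- hits > 0
  n_unmapped <- nrow(enhancers) -
    sum(GenomicRanges::countOverlaps(.as_gr(enhancers), .as_gr(dhs)) > 0)
  total <- nrow(assignment)
  n <- sum(enh_dhs)
  res <- lapply(sort(unique(assignment$cluster)), function(c) {
    in_c <- assignment$cluster == c
    size <- sum(in_c)
    x <- sum(enh_dhs & in_c)
    p0 <- size / total
    p <- if (size == 0L) 1 else pbinom(x - 1L, n, p0, lower.tail = FALSE)
    data.table::data.table(cluster = c, size = size, x = x, n = n,
                           p0 = p0, p_value = p)
  })
  out <- data.table::rbindlist(res)
  data.table::setattr(out, "n_unmapped", n_unmapped)
  out[]
}

## cross-validated score of one random-forest model
.rf_cv_score <- function(data, target, folds_idx, mode, num_trees, mtry,
                         seed) {
  scores <- vapply(seq_along(folds_idx), function(f) {
    test_idx <- folds_idx[[f]]
    train <- data[-test_idx, , drop = FALSE]
    test <- data[test_idx, , drop = FALSE]
    y_test <- test[[target]]
    fit <- ranger::ranger(
      stats::as.formula(paste(target, "~ .")), data = train,
      num.trees = num_trees, mtry = min(mtry, ncol(train) - 1L),
      seed = seed + f, num.threads = 1L,
      classification = FALSE)
    pred <- predict(fit, data = test, num.threads = 1L)$predictions
    if (mode == "regression") {
      sst <- sum((y_test - mean(y_test))^2)
      if (sst == 0) return(0)
      1 - sum((y_test - pred)^2) / sst
    } else {
      as.numeric(pROC::auc(pROC::roc(response = y_test, predictor = pred,
                                     quiet = TRUE, direction = "<")))
    }
  }, 0)
  mean(scores)
}

#' Greedy forward feature selection with random-forest models
#'
#' Starting from the base features, iteratively adds the candidate that
#' maximizes the cross-validated score of a random forest (default 100
#' trees, 3 variables tried per split): per-fold R-squared averaged over
#' folds in regression mode, or AUC for the binary above/below-median
#' target in classification mode. Fold assignment is seeded (stratified by
#' the median split in classification mode) and fixed across the whole
#' selection, so runs are reproducible.
#'
#' @param table feature table (data.frame).
#' @param target name of the numeric target column.
#' @param base_features always-included feature names.
#' @param candidates candidate feature names to select from.
#' @param n_add number of features to add (default 10).
#' @param folds number of CV folds (default 3).
#' @param mode `"regression"` (R-squared) or `"classification"` (AUC on the
#'   above-median indicator).
#' @param num_trees,mtry random-forest parameters (defaults 100, 3).
#' @param seed integer seed.
#' @return list: `selected` (ordered names) and `trace` (`data.table` of
#'   step, feature, score; plus the per-step runner-up scores as a list
#'   column `all_scores`).
#' @export
greedy_rf_selection <- function(table, target, base_features, candidates,
                                n_add = 10L, folds = 3L,
                                mode = c("regression", "classification"),
                                num_trees = 100L, mtry = 3L, seed = 1L) {
  mode <- match.arg(mode)
  table <- as.data.frame(table)
  if (length(candidates) < n_add) {
    warning("fewer candidates than n_add; selecting all")
    n_add <- length(candidates)
  }
  y <- table[[target]]
  if (mode == "classification") {
    table[[target]] <- as.integer(y > median(y))
  }
  folds_idx <- with_seed(seed, {
    if (mode == "classification") {
      # stratify folds on the median split
      idx0 <- sample(which(table[[target]] == 0L))
      idx1 <- sample(which(table[[target]] == 1L))
      f0 <- rep_len(seq_len(folds), length(idx0))
      f1 <- rep_len(seq_len(folds), length(idx1))
      lapply(seq_len(folds), function(f) c(idx0[f0 == f], idx1[f1 == f]))
    } else {
      idx <- sample(nrow(table))
      f <- rep_len(seq_len(folds), nrow(table))
      lapply(seq_len(folds), function(k) idx[f == k])
    }
  })
  selected <- character(0)
  trace <- list()
  remaining <- candidates
  for (step in seq_len(n_add)) {
    scores <- vapply(remaining, function(cand) {
      cols <- c(base_features, selected, cand, target)
      .rf_cv_score(table[, cols, drop = FALSE], target, folds_idx, mode,
                   num_trees, mtry, seed + 1000L * step)
    }, 0)
    best <- names(scores)[which.max(scores)]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    trace[[step]] <- data.table::data.table(
      step = step, feature = best, score = max(scores),
      all_scores = list(scores))
    if (!length(remaining)) break
  }
  list(selected = selected, trace = data.table::rbindlist(trace))
}

#' IQR-based upper outlier filter
#'
#' Drops values more than `t` interquartile ranges above the third
#' quartile (quartiles by linear interpolation). A zero IQR drops nothing,
#' with a warning.
#'
#' @param values numeric vector (length >= 4).
#' @param t IQR multiplier (default 50).
#' @return logical keep mask.
#' @export
iqr_outlier_filter <- function(values, t = 50) {
  if (length(values) < 4L) stop("need at least 4 values")
  q <- .quartiles(values)
  iqr <- q[2] - q[1]
  if (iqr == 0) {
    warning("zero IQR; nothing filtered")
    return(rep(TRUE, length(values)))
  }
  values <= q[2] + t * iqr
}

#' Pearson correlation of two coverage tracks over regions
#'
#' Correlates per-region mean coverages of two tracks.
#'
#' @param track_a,track_b coverage `RleList`s (see [coverage_track()]).
#' @param regions interval table (>= 2 regions).
#' @return Pearson correlation coefficient.
#' @export
coverage_correlation <- function(track_a, track_b, regions) {
  if (nrow(regions) < 2L) stop("need at least 2 regions")
  a <- region_occupancy(track_a, regions)
  b <- region_occupancy(track_b, regions)
  if (sd(a) == 0 || sd(b) == 0) stop("zero variance in region coverages")
  stats::cor(a, b)
}
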