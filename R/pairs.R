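## Ligation-pair records: reading/writing 4DN-style .pairs files,
## classification into mononucleosomal / distal / other, deduplication,
## subsampling and genomic binning.
##
## A pair table has columns readID, chrom1, pos1, chrom2, pos2, strand1,
## strand2 with mates in upper-triangular order: (chrom1, pos1) <=
## (chrom2, pos2). Positions are 0-based 5' read positions.

PAIR_COLS <- c("readID", "chrom1", "pos1", "chrom2", "pos2",
               "strand1", "strand2")

#' Column dialect for .pairs files
#'
#' Describes the order of columns in a tab-separated pairs file. The default
#' is the 4DN convention `readID chrom1 pos1 chrom2 pos2 strand1 strand2`.
#'
#' @param columns character vector naming the file's columns in order. Must
#'   contain `chrom1`, `pos1`, `chrom2`, `pos2`, `strand1`, `strand2`;
#'   other names are carried through, unknown positions can be labelled
#'   arbitrarily (e.g. `"ignore1"`).
#' @return an object of class `pairs_dialect`.
#' @export
pairs_dialect <- function(columns = PAIR_COLS) {
  required <- setdiff(PAIR_COLS, "readID")
  missing <- setdiff(required, columns)
  if (length(missing))
    stop("dialect must name columns: ", paste(missing, collapse = ", "))
  structure(list(columns = columns), class = "pairs_dialect")
}

#' Read ligation pairs from a .pairs file
#'
#' Header lines starting with `#` are skipped. Mates are reordered into the
#' upper-triangular convention. Records on chromosomes outside `chroms`
#' (when given) are dropped; the number dropped is available as
#' `attr(x, "skipped_chroms")`.
#'
#' @param path path to a plain or gzipped tab-separated pairs file.
#' @param dialect a [pairs_dialect()].
#' @param chroms optional character vector of allowed chromosome names.
#' @return `data.table` of pair records.
#' @export
read_pairs <- function(path, dialect = pairs_dialect(), chroms = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_header <- startsWith(lines, "#")
  n_header <- if (any(!is_header)) which(!is_header)[1] - 1L else length(lines)
  body <- lines[!is_header]
  if (!length(body)) {
    dt <- data.table::data.table(readID = character(), chrom1 = character(),
      pos1 = integer(), chrom2 = character(), pos2 = integer(),
      strand1 = character(), strand2 = character())
    return(dt)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ncols <- length(dialect$columns)
  if (any(nf < ncols)) {
    bad <- which(nf < ncols)[1]
    stop(sprintf("malformed pairs line %d: expected %d fields, found %d",
                 which(!is_header)[bad], ncols, nf[bad]))
  }
  mat <- matrix(unlist(lapply(fields, `[`, seq_len(ncols))),
                ncol = ncols, byrow = TRUE)
  colnames(mat) <- dialect$columns
  get_col <- function(nm) mat[, nm]
  parse_pos <- function(nm) {
    raw <- get_col(nm)
    val <- suppressWarnings(as.integer(raw))
    bad <- which(is.na(val) | suppressWarnings(as.numeric(raw)) != val)
    if (length(bad))
      stop(sprintf("malformed pairs line %d: non-integer %s '%s'",
                   which(!is_header)[bad[1]], nm, raw[bad[1]]))
    if (any(val < 0))
      stop(sprintf("malformed pairs line %d: negative position",
                   which(!is_header)[which(val < 0)[1]]))
    val
  }
  dt <- data.table::data.table(
    readID = if ("readID" %in% dialect$columns) get_col("readID")
             else paste0("r", seq_len(nrow(mat))),
    chrom1 = get_col("chrom1"), pos1 = parse_pos("pos1"),
    chrom2 = get_col("chrom2"), pos2 = parse_pos("pos2"),
    strand1 = get_col("strand1"), strand2 = get_col("strand2")
  )
  stopifnot(all(c(dt$strand1, dt$strand2) %in% c("+", "-")))
  dt <- order_mates(dt)
  skipped <- 0L
  if (!is.null(chroms)) {
    keep <- dt$chrom1 %in% chroms & dt$chrom2 %in% chroms
    skipped <- sum(!keep)
    if (skipped) message(skipped, " pair(s) on unlisted chromosomes skipped")
    dt <- dt[keep]
  }
  data.table::setattr(dt, "skipped_chroms", skipped)
  dt[]
}

#' Enforce upper-triangular mate order
#'
#' Swaps mates so that (chrom1, pos1) <= (chrom2, pos2); strand labels
#' travel with their mate.
#'
#' @param pairs pair table.
#' @return reordered `data.table`.
#' @export
order_mates <- function(pairs) {
  dt <- data.table::as.data.table(pairs)
  flip <- dt$chrom1 > dt$chrom2 | (dt$chrom1 == dt$chrom2 & dt$pos1 > dt$pos2)
  if (any(flip)) {
    dt[flip, c("chrom1", "pos1", "strand1", "chrom2", "pos2", "strand2") :=
         .(chrom2, pos2, strand2, chrom1, pos1, strand1)]
  }
  dt
}

#' Write pairs in 4DN .pairs format
#'
#' @param pairs pair table.
#' @param path output path.
#' @param chrom_sizes optional named vector, written as `#chromsize` headers.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, chrom_sizes = NULL) {
  hdr <- c("## pairs format v1.0",
           if (!is.null(chrom_sizes))
             sprintf("#chromsize: %s %d", names(chrom_sizes), chrom_sizes),
           paste("#columns:", paste(PAIR_COLS, collapse = " ")))
  writeLines(hdr, path)
  data.table::fwrite(data.table::as.data.table(pairs)[, PAIR_COLS, with = FALSE],
                     path, sep = "\t", col.names = FALSE, append = TRUE,
                     quote = FALSE, scipen = 50)
  invisible(path)
}

#' Classify ligation pairs
#'
#' Mononucleosomal pairs are cis, convergent (`+`/`-` in upper-triangular
#' order) and separated by more than 100 and less than 201 bp; distal pairs
#' are cis and separated by more than 5000 bp; everything else (including
#' all trans pairs) is `other`. Separation is `|pos2 - pos1|` on the stored
#' 5' positions.
#'
#' @param pairs pair table.
#' @return the table with a `pair_class` factor column
#'   (`mononucleosomal` / `distal` / `other`).
#' @export
classify_pairs <- function(pairs) {
  dt <- data.table::as.data.table(pairs)
  cis <- dt$chrom1 == dt$chrom2
  sep <- abs(dt$pos2 - dt$pos1)
  mono <- cis & dt$strand1 == "+" & dt$strand2 == "-" & sep > 100 & sep < 201
  distal <- cis & sep > 5000
  cls <- rep("other", nrow(dt))
  cls[distal] <- "distal"
  cls[mono] <- "mononucleosomal"   # mono and distal ranges cannot overlap
  dt$pair_class <- factor(cls, levels = c("mononucleosomal", "distal", "other"))
  dt
}

#' Per-class pair counts and summary fractions
#'
#' @param pairs classified pair table (see [classify_pairs()]).
#' @return list with per-class `counts`, fraction of cis pairs within 1 kb
#'   (`frac_within_1kb`) and fraction beyond 5 kb (`frac_beyond_5kb`).
#' @export
pair_class_stats <- function(pairs) {
  dt <- if ("pair_class" %in% names(pairs)) data.table::as.data.table(pairs)
        else classify_pairs(pairs)
  sep <- abs(dt$pos2 - dt$pos1)
  cis <- dt$chrom1 == dt$chrom2
  list(
    counts = as.list(table(dt$pair_class)),
    n = nrow(dt),
    frac_within_1kb = mean(cis & sep <= 1000),
    frac_beyond_5kb = mean(cis & sep > 5000)
  )
}

#' Deduplicate pair records
#'
#' Among records whose two mates both lie within `tolerance` bp of an
#' already-retained record with the same strand combination, only the first
#' is kept. Input must be sorted by (chrom1, pos1, chrom2, pos2).
#'
#' @param pairs sorted pair table.
#' @param tolerance positional tolerance in bp (default 0 = exact).
#' @return deduplicated `data.table`.
#' @export
deduplicate_pairs <- function(pairs, tolerance = 0L) {
  dt <- data.table::as.data.table(pairs)
  if (nrow(dt) < 2L) return(dt)
  o <- order(dt$chrom1, dt$pos1, dt$chrom2, dt$pos2, method = "radix")
  if (!identical(o, seq_len(nrow(dt))))
    stop("input to deduplicate_pairs() must be sorted by (chrom1,pos1,chrom2,pos2)")
  if (tolerance == 0L) {
    keep <- !duplicated(dt[, .(chrom1, pos1, strand1, chrom2, pos2, strand2)])
    return(dt[keep])
  }
  grp <- paste(dt$chrom1, dt$chrom2, dt$strand1, dt$strand2, sep = "\r")
  keep <- logical(nrow(dt))
  for (g in split(seq_len(nrow(dt)), grp)) {
    kept_p1 <- integer(0); kept_p2 <- integer(0)
    for (i in g) {
      dup <- length(kept_p1) &&
        any(abs(kept_p1 - dt$pos1[i]) <= tolerance &
            abs(kept_p2 - dt$pos2[i]) <= tolerance)
      if (!dup) {
        keep[i] <- TRUE
        kept_p1 <- c(kept_p1, dt$pos1[i]); kept_p2 <- c(kept_p2, dt$pos2[i])
      }
    }
  }
  dt[keep]
}

#' Bernoulli subsampling of pair records
#'
#' Each record is kept independently with probability `fraction`;
#' deterministic for a given seed.
#'
#' @param pairs pair table.
#' @param fraction keep probability in (0, 1].
#' @param seed integer seed.
#' @return subsampled `data.table`.
#' @export
subsample_pairs <- function(pairs, fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  dt <- data.table::as.data.table(pairs)
  keep <- with_seed(seed, runif(nrow(dt)) <= fraction)
  dt[keep]
}

#' Assign positions to fixed-width genomic bins
#'
#' Bins are 0-based half-open `[k*width, (k+1)*width)`.
#'
#' @param pos integer vector of positions (bp, >= 0).
#' @param width bin width in bp (default 250).
#' @param chrom optional chromosome name(s), recycled.
#' @return `data.table` with `chrom` (if given), `start`, `end`.
#' @export
assign_bin <- function(pos, width = 250L, chrom = NULL) {
  if (width <= 0) stop("`width` must be positive")
  if (any(pos < 0)) stop("positions must be non-negative")
  start <- as.integer(pos %/% width) * as.integer(width)
  out <- data.table::data.table(start = start, end = start + as.integer(width))
  if (!is.null(chrom)) out <- data.table::data.table(chrom = chrom, out)
  out
}

#' Tile a region with fixed-width bins
#'
#' @param chrom chromosome name.
#' @param start,end region bounds (0-based half-open).
#' @param width bin width (default 250).
#' @return `data.table` of bins; the last bin is clipped to `end`.
#' @export
make_bins <- function(chrom, start, end, width = 250L) {
  s <- seq(as.integer(start %/% width) * width, end - 1L, by = width)
  data.table::data.table(chrom = chrom, start = as.integer(s),
                         end = as.integer(pmin(s + width, end)))
}
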