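## Internal helpers: seeding, rounding, interval conversions, text-format IO.
## Coordinates are 0-based half-open everywhere in memory; conversion to the
## 1-based closed convention happens only at the GRanges boundary.

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages in reports use
#' conventional half-up rounding (60.65 -> 60.7).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## data.frame (chrom,start,end; 0-based half-open) -> GRanges
.as_gr <- function(df, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  sl <- if (is.null(chrom_sizes)) NA else chrom_sizes
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if (!is.null(chrom_sizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
    GenomeInfoDb::seqlengths(gr) <- chrom_sizes
  }
  gr
}

## GRanges -> data.table (0-based half-open)
.gr_as_dt <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

.check_chroms <- function(chroms, chrom_sizes, what = "region") {
  bad <- setdiff(unique(as.character(chroms)), names(chrom_sizes))
  if (length(bad))
    stop(sprintf("%s on unknown chromosome(s): %s", what,
                 paste(bad, collapse = ", ")))
  invisible(TRUE)
}

#' Read an ENCODE narrowPeak (or BED-like) file
#'
#' Columns beyond the first three are kept when present under their
#' narrowPeak names (name, score, strand, signalValue, pValue, qValue, peak).
#'
#' @param path file path (plain text).
#' @return `data.table` with 0-based half-open `start`/`end`.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  np_names <- c("chrom", "start", "end", "name", "score", "strand",
                "signalValue", "pValue", "qValue", "peak")
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  data.table::setnames(dt, np_names[seq_len(min(ncol(dt), 10L))])
  dt
}

#' Write intervals as BED / narrowPeak text
#'
#' @param df data.frame with `chrom`, `start`, `end` plus optional columns,
#'   written in the order given.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  data.table::fwrite(data.table::as.data.table(df), path, sep = "\t",
                     col.names = FALSE, quote = FALSE, scipen = 50)
  invisible(path)
}

## linear-interpolation quartiles (type 7), shared by the IQR filter
.quartiles <- function(x) stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
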