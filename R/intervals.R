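#' Read genomic intervals from BED or 1-based TSV
#'
#' All intervals are held internally as 0-based half-open `[start, end)`.
#' BED input is already in that convention; the `tsv1` dialect is 1-based
#' inclusive (as printed in many supplementary tables) and is shifted at the
#' boundary. Records whose converted `start >= end` are rejected.
#'
#' @param path File path. Three or more tab-separated columns:
#'   chrom, start, end, and optionally a label in column 4.
#' @param format `"bed"` (0-based half-open) or `"tsv1"` (1-based inclusive).
#' @param label Label applied when the file has no 4th column.
#' @return Tibble with columns `chrom`, `start`, `end`, `label`, `value`.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100", p)
#' read_intervals(p, "bed")
#' @export
read_intervals <- function(path, format = c("bed", "tsv1"), label = NA_character_) {
  format <- match.arg(format)
  # read.table with fill handles BED files whose optional columns appear on
  # only some rows
  df <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                          comment.char = "#", colClasses = "character",
                          na.strings = c("NA", ""))
  if (ncol(df) < 3) abort("interval file needs at least 3 columns")
  out <- tibble(
    chrom = as.character(df[[1]]),
    start = suppressWarnings(as.numeric(df[[2]])),
    end = suppressWarnings(as.numeric(df[[3]])),
    label = if (ncol(df) >= 4) as.character(df[[4]]) else label,
    value = if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NA_real_
  )
  if (format == "tsv1") {
    out$start <- out$start - 1
  }
  bad <- is.na(out$start) | is.na(out$end) |
    out$start >= out$end | out$start < 0
  if (any(bad)) {
    warn(sprintf("rejected %d interval record(s) with start >= end", sum(bad)))
    out <- out[!bad, ]
  }
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `label`, `value` (written as BED name/score columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  df <- tibble(
    chrom = intervals$chrom,
    start = format(intervals$start, scientific = FALSE, trim = TRUE),
    end = format(intervals$end, scientific = FALSE, trim = TRUE)
  )
  if ("label" %in% names(intervals)) df$name <- intervals$label
  if ("value" %in% names(intervals) && !all(is.na(intervals$value))) {
    df$score <- intervals$value
  }
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

# -- internal interval arithmetic (IRanges behind a tibble surface) ---------

# Collapse (chrom, start, end) into a single IRanges space by offsetting each
# chromosome past the largest coordinate seen, so cross-chromosome intervals
# can never touch. IRanges coordinates are 32-bit, so the offset unit is
# derived from the data rather than fixed.
.offset_unit <- function(...) {
  m <- max(1, unlist(lapply(list(...), function(d) d$end)), na.rm = TRUE)
  m + 2
}

.ivl_ranges <- function(df, chrom_levels, unit) {
  off <- (match(df$chrom, chrom_levels) - 1) * unit
  # [start, end) half-open -> 1-based closed IRanges
  IRanges::IRanges(start = off + df$start + 1, end = off + df$end)
}

.chrom_levels <- function(...) {
  unique(unlist(lapply(list(...), function(d) unique(d$chrom))))
}

# pairs (i, j) of a-intervals overlapping b-intervals by >= 1 bp
interval_overlap_pairs <- function(a, b) {
  lev <- .chrom_levels(a, b)
  unit <- .offset_unit(a, b)
  hits <- IRanges::findOverlaps(.ivl_ranges(a, lev, unit),
                                .ivl_ranges(b, lev, unit))
  tibble(i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits))
}

# merge overlapping or adjacent intervals into maximal intervals
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(tibble(chrom = character(), start = numeric(), end = numeric()))
  lev <- .chrom_levels(df)
  unit <- .offset_unit(df)
  red <- IRanges::reduce(.ivl_ranges(df, lev, unit))
  s <- IRanges::start(red) - 1
  e <- IRanges::end(red)
  idx <- floor(s / unit) + 1
  tibble(
    chrom = lev[idx],
    start = s - (idx - 1) * unit,
    end = e - (idx - 1) * unit
  ) |> arrange(.data$chrom, .data$start)
}

interval_total_bases <- function(df) {
  m <- merge_intervals(df)
  sum(m$end - m$start)
}

# logical: is each (chrom, pos) point inside any interval?
in_intervals <- function(chrom, pos, intervals) {
  if (nrow(intervals) == 0 || length(pos) == 0) return(rep(FALSE, length(pos)))
  pts <- tibble(chrom = chrom, start = pos, end = pos + 1)
  lev <- .chrom_levels(pts, intervals)
  unit <- .offset_unit(pts, intervals)
  IRanges::overlapsAny(.ivl_ranges(pts, lev, unit),
                       .ivl_ranges(intervals, lev, unit))
}

# per-query count of overlapping subject intervals (>= 1 bp)
count_overlaps_ivl <- function(query, subject) {
  lev <- .chrom_levels(query, subject)
  unit <- .offset_unit(query, subject)
  IRanges::countOverlaps(.ivl_ranges(query, lev, unit),
                         .ivl_ranges(subject, lev, unit))
}
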