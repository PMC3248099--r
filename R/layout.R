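#' Describe a genome as an ordered set of chromosomes
#'
#' A genome layout is the single source of truth for chromosome names,
#' lengths and ploidy used by window tiling, density calculations and
#' permutation placement. Coordinates everywhere in this package are
#' 0-based, half-open.
#'
#' @param chrom Character vector of unique chromosome names, in order.
#' @param length Integer vector of chromosome lengths in bp (> 0).
#' @param sex_chroms Character vector naming the sex chromosomes (subset of
#'   `chrom`). On a male sample these are haploid, and heterozygous calls on
#'   them are treated as artifacts by [drop_sex_het()].
#'
#' @return A tibble with columns `chrom`, `length`, `sex` of class
#'   `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chrX"), c(4e6, 1.5e6), sex_chroms = "chrX")
#' @export
genome_layout <- function(chrom, length, sex_chroms = character()) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  if (any(length <= 0)) abort("chromosome lengths must be > 0")
  if (!all(sex_chroms %in% chrom)) abort("sex_chroms must appear in chrom")
  out <- tibble(
    chrom = as.character(chrom),
    length = as.numeric(length),
    sex = chrom %in% sex_chroms
  )
  class(out) <- c("genome_layout", class(out))
  out
}

#' Read / write a genome layout TSV
#'
#' The TSV has columns `chrom`, `length` and optionally `sex` (TRUE/FALSE).
#'
#' @param path File path.
#' @return [read_genome_layout()] returns a `genome_layout` tibble;
#'   [write_genome_layout()] returns `path` invisibly.
#' @export
read_genome_layout <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  sex <- if ("sex" %in% names(df)) df$chrom[as.logical(df$sex)] else character()
  genome_layout(df$chrom, df$length, sex_chroms = sex)
}

#' @rdname read_genome_layout
#' @param layout A `genome_layout`.
#' @export
write_genome_layout <- function(layout, path) {
  readr::write_tsv(layout, path)
  invisible(path)
}

genome_size <- function(layout) sum(layout$length)

check_chroms <- function(chrom, layout, what = "input") {
  bad <- setdiff(unique(chrom), layout$chrom)
  if (length(bad) > 0) {
    abort(paste0(
      what, " uses chromosomes absent from the layout: ",
      paste(bad, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

#' Tile a genome into fixed non-overlapping windows
#'
#' @param layout A [genome_layout()].
#' @param window Window size in bp. The final window on each chromosome is
#'   truncated at the chromosome end.
#' @return Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
tile_genome <- function(layout, window) {
  purrr::map(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq(0, len - 1, by = window)
    tibble(
      chrom = layout$chrom[i],
      start = starts,
      end = pmin(starts + window, len)
    )
  }) |> purrr::list_rbind()
}
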