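#' Read SNP-array genotypes
#'
#' The TSV has columns `marker_id`, `chrom`, `pos` (0-based by default),
#' `allele_a`, `allele_b`, `call`, `chip`. A call is an unordered allele
#' pair written `"A/G"`; no-calls are empty or `"."` and are read as `NA`.
#' Calls are canonicalized so the two alleles are in alphabetical order.
#'
#' @param path File path.
#' @param based Either `0` (default) or `1`; 1-based positions are shifted
#'   down at the boundary.
#' @return Tibble with the columns above.
#' @export
read_chip_genotypes <- function(path, based = 0) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(chrom = "c", call = "c"))
  df$pos <- df$pos - based
  df$call <- canonical_call(df$call)
  bad <- !is.na(df$call) &
    !purrr::map2_lgl(df$call, paste(df$allele_a, df$allele_b),
                     function(cl, ab) {
                       al <- strsplit(cl, "/", fixed = TRUE)[[1]]
                       all(al %in% strsplit(ab, " ", fixed = TRUE)[[1]])
                     })
  if (any(bad)) abort("chip calls contain alleles outside {allele_a, allele_b}")
  tibble::as_tibble(df)
}

#' @rdname read_chip_genotypes
#' @param chip Chip genotype tibble.
#' @export
write_chip_genotypes <- function(chip, path) {
  out <- chip
  out$call <- ifelse(is.na(out$call), ".", out$call)
  readr::write_tsv(out, path)
  invisible(path)
}

# sort the two alleles of "G/A" -> "A/G"; "."/"" -> NA
canonical_call <- function(call) {
  vapply(call, function(x) {
    if (is.na(x) || x %in% c(".", "", "./.")) return(NA_character_)
    paste(sort(strsplit(x, "/", fixed = TRUE)[[1]]), collapse = "/")
  }, character(1), USE.NAMES = FALSE)
}

#' Pair genotypes of two chips at their shared markers
#'
#' @param chip_a,chip_b Chip genotype tibbles ([read_chip_genotypes()]).
#'   Markers are matched by `marker_id`; no-calls on either chip are
#'   dropped.
#' @return Tibble with `marker_id`, `call_a`, `call_b`.
#' @export
pair_chip_genotypes <- function(chip_a, chip_b) {
  inner_join(
    chip_a |> filter(!is.na(.data$call)) |> select("marker_id", call_a = "call"),
    chip_b |> filter(!is.na(.data$call)) |> select("marker_id", call_b = "call"),
    by = "marker_id"
  )
}

#' Chip-versus-chip genotyping error rate
#'
#' Two arrays genotyping the same individual should agree at every shared
#' marker; assuming each discordance reflects one wrong genotype, the
#' discordance fraction estimates the per-genotype chip error rate.
#' Discordance counts any difference between the unordered allele pairs,
#' including het/hom disagreements.
#'
#' @param paired Paired genotypes from [pair_chip_genotypes()] (columns
#'   `call_a`, `call_b`), no-calls excluded.
#' @return A one-row tibble with `n_shared`, `n_discordant`, `error_rate`.
#' @examples
#' paired <- tibble::tibble(call_a = c("A/G", "C/C"), call_b = c("A/G", "C/T"))
#' chip_error_rate(paired)
#' @export
chip_error_rate <- function(paired) {
  if (nrow(paired) == 0) abort("no shared markers")
  disc <- canonical_call(paired$call_a) != canonical_call(paired$call_b)
  tibble(
    n_shared = nrow(paired),
    n_discordant = sum(disc),
    error_rate = sum(disc) / nrow(paired)
  )
}

#' Drop heterozygous calls on haploid sex chromosomes
#'
#' In a male mammal the X (outside the pseudoautosomal region) is haploid,
#' so heterozygous genotypes there are artifacts and are removed before any
#' concordance or ROH summary.
#'
#' @param df A call tibble (`zygosity` column) or chip genotype tibble
#'   (`call` column, het = two different alleles).
#' @param layout A [genome_layout()] whose `sex` column flags the haploid
#'   chromosomes.
#' @return The tibble without sex-chromosome heterozygotes.
#' @export
drop_sex_het <- function(df, layout) {
  sex_chr <- layout$chrom[layout$sex]
  if ("zygosity" %in% names(df)) {
    het <- df$zygosity == "het"
  } else {
    al <- strsplit(ifelse(is.na(df$call), "N/N", df$call), "/", fixed = TRUE)
    het <- vapply(al, function(x) length(unique(x)) > 1, logical(1))
  }
  df[!(het & df$chrom %in% sex_chr), ]
}
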