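#' Overview of detected variation by class
#'
#' Builds a per-method summary table: for each variant class the number of
#' variants, the min/median/max event size and the total bases affected
#' (SNPs affect 1 bp each, indels their size, interval classes their
#' length). Classes are *not* deduplicated against each other: the totals
#' are plain column sums of the per-method rows.
#'
#' @param snps SNP call tibble (or `NULL`).
#' @param indels Indel call tibble (sizes from `ref`/`alt`; or `NULL`).
#' @param svs Named list of SV interval tibbles, one per method (each with
#'   `start`, `end`), or `NULL`.
#' @param cnvs CNV interval tibble, or `NULL`.
#' @return Tibble of class `variation_overview`: `method`, `n`, `min_size`,
#'   `median_size`, `max_size`, `total_bases`.
#' @export
variation_overview <- function(snps = NULL, indels = NULL, svs = NULL,
                               cnvs = NULL) {
  row_for <- function(method, sizes) {
    tibble(method = method, n = length(sizes),
           min_size = if (length(sizes)) min(sizes) else NA_real_,
           median_size = if (length(sizes)) median(sizes) else NA_real_,
           max_size = if (length(sizes)) max(sizes) else NA_real_,
           total_bases = sum(sizes))
  }
  rows <- list()
  if (!is.null(snps)) rows$snp <- row_for("snp", rep(1, nrow(snps)))
  if (!is.null(indels)) rows$indel <- row_for("indel", indel_size(indels))
  if (!is.null(svs)) {
    for (nm in names(svs)) {
      rows[[nm]] <- row_for(nm, svs[[nm]]$end - svs[[nm]]$start)
    }
  }
  if (!is.null(cnvs)) rows$cnv <- row_for("cnv", cnvs$end - cnvs$start)
  out <- purrr::list_rbind(rows)
  class(out) <- c("variation_overview", class(out))
  out
}

#' Totals of a variation overview
#'
#' @param overview A [variation_overview()]-shaped tibble (columns
#'   `method`, `n`, `total_bases`); the SNP row is identified by
#'   `method == "snp"` (or a `type` column equal to `"SNP"`).
#' @return One-row tibble: `n_total`, `bases_total`, `bases_snp`,
#'   `bases_structural` (total bases minus SNP bases).
#' @export
variation_totals <- function(overview) {
  is_snp <- if ("type" %in% names(overview)) {
    toupper(overview$type) == "SNP"
  } else {
    overview$method == "snp"
  }
  tibble(
    n_total = sum(overview$n),
    bases_total = sum(overview$total_bases),
    bases_snp = sum(overview$total_bases[is_snp]),
    bases_structural = sum(overview$total_bases[!is_snp])
  )
}
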