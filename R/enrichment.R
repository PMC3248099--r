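#' Variant density enrichment in a region set
#'
#' Compares the variant density inside a set of regions (e.g. CNV
#' duplications, CpG islands, the X chromosome) with the density outside
#' and genome-wide. Densities are variants per `per` bp; the departure from
#' proportional allocation is tested with a 1-df chi-square of the observed
#' in/out counts against the expectation from the base fractions.
#'
#' @param variants Call tibble (any variant type; each row one variant).
#' @param regions Interval tibble; must lie within the layout and cover
#'   more than 0 bases.
#' @param layout A [genome_layout()].
#' @param per Density unit in bp (default 10 kb).
#' @param correct Yates continuity correction (default off).
#' @return List of class `enrichment_result`: `n_in`, `n_out`,
#'   `density_in`, `density_out`, `density_genome`, `fold` (in/out),
#'   `statistic`, `p_value`.
#' @export
region_density_enrichment <- function(variants, regions, layout, per = 1e4,
                                      correct = FALSE) {
  check_chroms(regions$chrom, layout, "regions")
  bases_in <- interval_total_bases(regions)
  if (bases_in <= 0) abort("regions cover 0 bases")
  total <- genome_size(layout)
  bases_out <- total - bases_in
  inside <- in_intervals(variants$chrom, variants$pos, regions)
  n_in <- sum(inside)
  n_out <- sum(!inside)
  ct <- suppressWarnings(
    chisq.test(c(n_in, n_out), p = c(bases_in, bases_out) / total,
               correct = correct)
  )
  structure(
    list(
      n_in = n_in, n_out = n_out,
      bases_in = bases_in, bases_out = bases_out,
      density_in = n_in / (bases_in / per),
      density_out = n_out / (bases_out / per),
      density_genome = (n_in + n_out) / (total / per),
      fold = (n_in / bases_in) / (n_out / bases_out),
      statistic = unname(ct$statistic), p_value = ct$p.value
    ),
    class = "enrichment_result"
  )
}

#' Windowed SNP-indel density correlation
#'
#' Counts SNPs and indels in fixed genomic windows and reports the Pearson
#' correlation of the two count series across windows.
#'
#' @param snps,indels Call tibbles.
#' @param layout A [genome_layout()].
#' @param window Window size, bp (default 20 kb). At least 2 windows are
#'   required.
#' @return List of class `density_correlation`: `r`, `r_squared`,
#'   `p_value`, `n_windows`, and the per-window count tibble in `windows`.
#'   Zero variance in either series yields `NA` with a warning.
#' @export
windowed_density_correlation <- function(snps, indels, layout, window = 2e4) {
  grid <- tile_genome(layout, window)
  if (nrow(grid) < 2) abort("need at least 2 windows")
  count_in <- function(v) {
    out <- integer(nrow(grid))
    for (chr in unique(grid$chrom)) {
      gi <- which(grid$chrom == chr)
      pos <- v$pos[v$chrom == chr]
      if (length(pos) == 0) next
      # fixed tiling: window index is floor(pos / window) + 1
      out[gi] <- tabulate(floor(pos / window) + 1, nbins = length(gi))
    }
    out
  }
  grid$n_snp <- count_in(snps)
  grid$n_indel <- count_in(indels)
  if (stats::sd(grid$n_snp) == 0 || stats::sd(grid$n_indel) == 0) {
    warn("zero variance in a count series; correlation undefined")
    res <- list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_)
  } else {
    ct <- cor.test(grid$n_snp, grid$n_indel, method = "pearson")
    res <- list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
                p_value = ct$p.value)
  }
  structure(c(res, list(n_windows = nrow(grid), windows = grid)),
            class = "density_correlation")
}
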