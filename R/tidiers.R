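#' @method tidy venn_partition
#' @export
tidy.venn_partition <- function(x, ...) as_tibble(x)

#' @method tidy concordance_summary
#' @export
tidy.concordance_summary <- function(x, ...) as_tibble(x)

#' @method glance concordance_summary
#' @export
glance.concordance_summary <- function(x, ...) {
  tibble(detection_rate = attr(x, "detection_rate"),
         n_total = attr(x, "n_total"))
}

#' @method tidy fpr_report
#' @export
tidy.fpr_report <- function(x, ...) as_tibble(x)

#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    region = c("in", "out", "genome"),
    n = c(x$n_in, x$n_out, x$n_in + x$n_out),
    bases = c(x$bases_in, x$bases_out, x$bases_in + x$bases_out),
    density = c(x$density_in, x$density_out, x$density_genome)
  )
}

#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(fold = x$fold, statistic = x$statistic, p_value = x$p_value)
}

#' @method tidy threen_test
#' @export
tidy.threen_test <- function(x, ...) {
  as_tibble(x$table, rownames = "group")
}

#' @method glance threen_test
#' @export
glance.threen_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         frac_3n_coding = x$frac_3n_coding,
         frac_3n_background = x$frac_3n_background)
}

#' @method tidy density_correlation
#' @export
tidy.density_correlation <- function(x, ...) x$windows

#' @method glance density_correlation
#' @export
glance.density_correlation <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r_squared, p_value = x$p_value,
         n_windows = x$n_windows)
}

#' @method tidy perm_enrichment
#' @export
tidy.perm_enrichment <- function(x, ...) {
  tibble(perm = seq_along(x$null), n_genes = x$null)
}

#' @method glance perm_enrichment
#' @export
glance.perm_enrichment <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean, fold = x$fold,
         p_value = x$p_value, n_perm = x$n_perm)
}

#' @method tidy cnv_overlap
#' @export
tidy.cnv_overlap <- function(x, ...) x$venn

#' @method glance cnv_overlap
#' @export
glance.cnv_overlap <- function(x, ...) {
  tibble(n_cnvs = nrow(x$cnvs), n_shared = sum(x$cnvs$shared),
         n_consensus_regions = nrow(x$consensus))
}

#' @method tidy cross_assembly_report
#' @export
tidy.cross_assembly_report <- function(x, ...) x$report

#' @method glance cross_assembly_report
#' @export
glance.cross_assembly_report <- function(x, ...) {
  tibble(before = sum(x$report$before), after = sum(x$report$after),
         overall_reduction_pct = x$overall_reduction_pct)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Region density enrichment: fold = %.3g (in %.4g vs out %.4g per unit), chi-square p = %.3g\n",
    x$fold, x$density_in, x$density_out, x$p_value
  ))
  invisible(x)
}

#' @export
print.perm_enrichment <- function(x, ...) {
  cat(sprintf(
    "Permutation gene enrichment: observed %d genes, null mean %.2f, fold = %.3g, p = %.3g (%d permutations)\n",
    x$observed, x$null_mean, x$fold, x$p_value, x$n_perm
  ))
  invisible(x)
}

#' @export
print.threen_test <- function(x, ...) {
  cat(sprintf(
    "3n indel enrichment: coding %.1f%% vs background %.1f%% frame-preserving; chi-square %.2f, p = %.3g\n",
    100 * x$frac_3n_coding, 100 * x$frac_3n_background, x$statistic, x$p_value
  ))
  invisible(x)
}

#' @export
print.cross_assembly_report <- function(x, ...) {
  cat(sprintf("Cross-assembly SV filter: %d -> %d (%.1f%% reduction)\n",
              sum(x$report$before), sum(x$report$after),
              x$overall_reduction_pct))
  print(x$report)
  invisible(x)
}

#' @export
print.density_correlation <- function(x, ...) {
  cat(sprintf(
    "Windowed density correlation over %d windows: r = %.3f, R^2 = %.3f, p = %.3g\n",
    x$n_windows, x$r, x$r_squared, x$p_value
  ))
  invisible(x)
}
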