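#' Plot the log2 read-depth profile with CNV calls
#'
#' @param object A [call_cnv_readdepth()] result.
#' @param ... Unused.
#' @return A ggplot: per-window log2 ratio with called duplication and
#'   deletion segments overlaid.
#' @method autoplot cnv_calls
#' @export
autoplot.cnv_calls <- function(object, ...) {
  prof <- attr(object, "profile")
  mid <- (prof$start + prof$end) / 2
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = mid, y = .data$log2_ratio)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "log2 read-depth ratio")
  if (nrow(object) > 0) {
    p <- p + ggplot2::geom_segment(
      data = as_tibble(object),
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$mean_log2, yend = .data$mean_log2,
                   colour = .data$cnv_type),
      linewidth = 1.5, inherit.aes = FALSE
    )
  }
  p
}

#' Null distribution of the permutation gene-enrichment test
#'
#' @param object A [gene_enrichment_permutation()] result.
#' @param ... Unused.
#' @return A ggplot histogram of null gene counts with the observed count
#'   marked.
#' @method autoplot perm_enrichment
#' @export
autoplot.perm_enrichment <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$n_genes)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "genes overlapped under random placement",
                  y = "permutations",
                  subtitle = sprintf("observed = %d, fold = %.2f, p = %.3g",
                                     object$observed, object$fold,
                                     object$p_value))
}

#' Concordance category counts by chip zygosity
#'
#' @param object A [concordance_summary()].
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @method autoplot concordance_summary
#' @export
autoplot.concordance_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$category, y = .data$n,
                               fill = .data$chip_zygosity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "sites (log scale)", fill = "chip call")
}

#' Minimum-allele-percentage distribution per caller
#'
#' Misalignment-driven false heterozygotes cluster at low MAP; comparing
#' callers on a trusted homozygous region makes the contrast visible.
#'
#' @param calls Het call tibble with `ad_ref`, `ad_alt` and `caller`.
#' @return A ggplot density plot of MAP by caller.
#' @export
plot_map_distribution <- function(calls) {
  ggplot2::ggplot(map_values(calls),
                  ggplot2::aes(x = .data$map, colour = .data$caller)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "minimum allele percentage", y = "density")
}
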