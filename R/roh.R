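#' Parameters for the sliding-window ROH scan
#'
#' Defaults follow the classic genome-scan settings for a deeply inbred
#' mammalian genome: 1 Mb windows advanced in 200 kb steps, a window
#' qualifying as homozygous when its heterozygote count is at most one
#' tenth of its homozygote count.
#'
#' @param window Window size, bp.
#' @param step Step size, bp (must be <= `window`).
#' @param max_het_hom_ratio Maximum het/hom ratio for a qualifying window,
#'   applied multiplicatively (`het <= ratio * hom`) so windows with zero
#'   homozygotes are handled without division.
#' @param min_snps_per_window Minimum SNP calls for a window to be
#'   evaluated; sparser windows never qualify.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window = 1e6, step = 2e5, max_het_hom_ratio = 0.1,
                       min_snps_per_window = 20) {
  if (step > window) abort("step must be <= window")
  if (max_het_hom_ratio <= 0 || max_het_hom_ratio >= 1) {
    abort("max_het_hom_ratio must be in (0, 1)")
  }
  if (min_snps_per_window < 1) abort("min_snps_per_window must be >= 1")
  structure(
    list(window = window, step = step,
         max_het_hom_ratio = max_het_hom_ratio,
         min_snps_per_window = min_snps_per_window),
    class = "roh_params"
  )
}

#' Detect runs of homozygosity with a sliding window
#'
#' Scans each chromosome with overlapping windows; a window qualifies when
#' it holds at least `min_snps_per_window` SNP calls and its heterozygote
#' count is at most `max_het_hom_ratio` times its homozygote count.
#' Overlapping or adjacent qualifying windows are merged into maximal
#' intervals (first window start to last window end). Partial windows at a
#' chromosome end are evaluated if at least half a window remains.
#'
#' @param calls SNP call tibble for one individual (`zygosity` of `het` or
#'   `hom_alt`; homozygous-reference records are ignored).
#' @param layout A [genome_layout()]; calls on chromosomes missing from it
#'   are an error.
#' @param params An [roh_params()].
#' @return Interval tibble (`chrom`, `start`, `end`, `label = "ROH"`,
#'   `value` = NA), non-overlapping and sorted. Output is invariant to the
#'   input row order.
#' @export
detect_roh <- function(calls, layout, params = roh_params()) {
  check_chroms(calls$chrom, layout, "calls")
  calls <- filter(calls, .data$vtype == "snp",
                  .data$zygosity %in% c("het", "hom_alt"))
  res <- purrr::map(seq_len(nrow(layout)), function(i) {
    chr <- layout$chrom[i]
    len <- layout$length[i]
    cc <- calls[calls$chrom == chr, ]
    starts <- seq(0, max(0, len - 1), by = params$step)
    ends <- pmin(starts + params$window, len)
    keep_w <- (ends - starts) >= params$window / 2
    starts <- starts[keep_w]
    ends <- ends[keep_w]
    if (length(starts) == 0) return(NULL)
    pos <- sort(cc$pos)
    het_pos <- sort(cc$pos[cc$zygosity == "het"])
    n_in <- function(p, s, e) {
      findInterval(e - 1e-9, p) - findInterval(s - 1e-9, p)
    }
    n_all <- n_in(pos, starts, ends)
    n_het <- n_in(het_pos, starts, ends)
    n_hom <- n_all - n_het
    ok <- n_all >= params$min_snps_per_window &
      n_het <= params$max_het_hom_ratio * n_hom
    if (!any(ok)) return(NULL)
    merge_intervals(tibble(chrom = chr, start = starts[ok], end = ends[ok]))
  }) |> purrr::list_rbind()
  if (is.null(res) || nrow(res) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  label = character(), value = numeric()))
  }
  res |> mutate(label = "ROH", value = NA_real_) |>
    arrange(.data$chrom, .data$start)
}

#' Fraction of the genome inside a set of intervals
#'
#' @param intervals Interval tibble (e.g. ROH calls).
#' @param layout A [genome_layout()].
#' @return Total merged interval bases divided by genome size.
#' @export
genome_fraction <- function(intervals, layout) {
  interval_total_bases(intervals) / genome_size(layout)
}

#' Heterozygote false-positive rate inside a trusted IBD region
#'
#' A recent identity-by-descent segment is homozygous by construction, so
#' heterozygous calls inside it are (almost all) false positives. The rate
#' is the fraction of all SNP calls in the region that are heterozygous.
#' For sub-intervals known to be identical to the reference sequence, every
#' call of any kind is spurious; a homozygote FPR over such intervals is
#' reported when they are supplied.
#'
#' @param calls SNP call tibble, possibly for several callers.
#' @param ibd Interval tibble delimiting the trusted IBD region(s).
#' @param ref_identical Optional interval tibble of reference-identical
#'   sub-regions for the homozygote FPR.
#' @param per_mb If `TRUE`, additionally report rates per Mb of IBD
#'   sequence rather than only per called SNP.
#' @return Tibble of class `fpr_report`, one row per caller: `caller`,
#'   `n_het`, `n_hom`, `fpr_het`, and `fpr_hom`/`het_per_mb` when
#'   applicable. Callers with no calls in the region get `NA` rates with a
#'   warning.
#' @export
fpr_in_ibd <- function(calls, ibd, ref_identical = NULL, per_mb = FALSE) {
  calls <- filter(calls, .data$vtype == "snp")
  inside <- calls[in_intervals(calls$chrom, calls$pos, ibd), ]
  mb <- interval_total_bases(ibd) / 1e6
  out <- inside |>
    group_by(.data$caller) |>
    summarise(
      n_het = sum(.data$zygosity == "het"),
      n_hom = sum(.data$zygosity == "hom_alt"),
      .groups = "drop"
    ) |>
    mutate(fpr_het = ifelse(.data$n_het + .data$n_hom > 0,
                            .data$n_het / (.data$n_het + .data$n_hom), NA_real_))
  missing <- setdiff(unique(calls$caller), out$caller)
  if (length(missing) > 0) {
    warn(paste0("no calls inside IBD for: ", paste(missing, collapse = ", ")))
    out <- bind_rows(out, tibble(caller = missing, n_het = 0L, n_hom = 0L,
                                 fpr_het = NA_real_))
  }
  if (per_mb) out$het_per_mb <- out$n_het / mb
  if (!is.null(ref_identical)) {
    hom <- calls[in_intervals(calls$chrom, calls$pos, ref_identical), ] |>
      group_by(.data$caller) |>
      summarise(fpr_hom = sum(.data$zygosity == "hom_alt") / n(),
                .groups = "drop")
    out <- left_join(out, hom, by = "caller")
  }
  class(out) <- c("fpr_report", class(out))
  out
}

#' Minimum allele percentage (MAP) of heterozygous calls
#'
#' MAP is the fraction of reads covering the less-covered allele of a
#' heterozygote; misalignment-driven false heterozygotes typically show a
#' much lower MAP than genuine ones.
#'
#' @param calls Het call tibble with `ad_ref`, `ad_alt`.
#' @return `calls` with added `map` (min allele depth over total) and
#'   `vaf` (variant-allele fraction) columns.
#' @export
map_values <- function(calls) {
  tot <- calls$ad_ref + calls$ad_alt
  if (any(is.na(tot)) || any(tot <= 0)) {
    abort("all calls need positive total allele depth")
  }
  calls$map <- pmin(calls$ad_ref, calls$ad_alt) / tot
  calls$vaf <- calls$ad_alt / tot
  calls
}

#' Post-hoc filter for heterozygous calls
#'
#' Removes likely misalignment artifacts among heterozygous SNPs: a call is
#' kept only with coverage of at least `min_coverage` reads (i.e. coverage
#' > 2 at the default) and a variant-allele read fraction strictly above
#' `min_variant_frequency`.
#'
#' @param calls Het SNP call tibble with `depth`, `ad_ref`, `ad_alt`.
#'   Calls with missing depth are dropped with a warning.
#' @param min_coverage Minimum kept depth (default 3).
#' @param min_variant_frequency Variant-allele fraction threshold
#'   (default 0.35, exclusive).
#' @return The filtered tibble.
#' @export
filter_het_calls <- function(calls, min_coverage = 3,
                             min_variant_frequency = 0.35) {
  nodepth <- is.na(calls$depth)
  if (any(nodepth)) {
    warn(sprintf("dropped %d call(s) with missing depth", sum(nodepth)))
    calls <- calls[!nodepth, ]
  }
  vaf <- calls$ad_alt / (calls$ad_ref + calls$ad_alt)
  calls[calls$depth >= min_coverage & vaf > min_variant_frequency, ]
}
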