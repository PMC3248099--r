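#' Parameters for read-depth CNV calling
#'
#' Defaults reproduce the classic read-depth rule: a window is CNV-like
#' when the |log2 ratio| of normalized read counts exceeds 1, and a CNV is
#' reported when at least 5 consecutive windows agree. Note that a 2-fold
#' gain (copy number 4 against a diploid reference) has an expected log2
#' ratio of exactly 1, so the strict default threshold sits on that
#' boundary; pass a lower `min_abs_log2` to target 2-fold events.
#'
#' @param min_abs_log2 Qualifying threshold on |log2 ratio| (exclusive).
#' @param min_consecutive Minimum run length in windows.
#' @param pseudocount Added to both counts for zero-safe ratios.
#' @param min_total_reads_per_window Windows with fewer combined raw reads
#'   are skipped (they neither qualify nor extend runs).
#' @return A list of class `rd_params`.
#' @export
rd_params <- function(min_abs_log2 = 1.0, min_consecutive = 5,
                      pseudocount = 0.5, min_total_reads_per_window = 10) {
  if (min_abs_log2 <= 0) abort("min_abs_log2 must be > 0")
  if (min_consecutive < 1) abort("min_consecutive must be >= 1")
  structure(
    list(min_abs_log2 = min_abs_log2, min_consecutive = min_consecutive,
         pseudocount = pseudocount,
         min_total_reads_per_window = min_total_reads_per_window),
    class = "rd_params"
  )
}

#' Call CNVs from windowed read depth of a test/reference sample pair
#'
#' Computes, per window, `log2((c_t/N_t) / (c_r/N_r))` with a pseudocount
#' added to both counts (N = total mapped reads per sample), then merges
#' maximal runs of at least `min_consecutive` consecutive qualifying
#' windows of consistent sign into CNV calls. A duplication run is never
#' joined to an adjacent deletion run.
#'
#' @param windows Window count tibble: `chrom`, `start`, `end`,
#'   `count_test`, `count_ref`, on a single shared grid (sorted, non-
#'   overlapping within chromosome).
#' @param params An [rd_params()].
#' @return Tibble of class `cnv_calls`: `chrom`, `start`, `end`,
#'   `cnv_type` (`duplication`/`deletion`), `mean_log2`, `n_windows`,
#'   `platform = "readdepth"`. The per-window log2 profile is attached as
#'   attribute `profile` (used by [autoplot.cnv_calls()]).
#' @examples
#' w <- tibble::tibble(chrom = "chr1", start = 0:9 * 1000, end = 1:10 * 1000,
#'                     count_test = c(rep(100, 3), rep(400, 5), 100, 100),
#'                     count_ref = 100)
#' call_cnv_readdepth(w)
#' @export
call_cnv_readdepth <- function(windows, params = rd_params()) {
  req <- c("chrom", "start", "end", "count_test", "count_ref")
  if (!all(req %in% names(windows))) abort("windows lack required columns")
  if (sum(windows$count_ref) == 0) abort("reference counts are all zero")
  if (is.unsorted(order(windows$chrom, windows$start))) {
    windows <- arrange(windows, .data$chrom, .data$start)
  }
  n_t <- sum(windows$count_test)
  n_r <- sum(windows$count_ref)
  pc <- params$pseudocount
  windows$log2_ratio <- log2(((windows$count_test + pc) / n_t) /
                               ((windows$count_ref + pc) / n_r))
  skipped <- (windows$count_test + windows$count_ref) <
    params$min_total_reads_per_window
  qual <- !skipped & abs(windows$log2_ratio) > params$min_abs_log2
  sgn <- sign(windows$log2_ratio)
  # run id: consecutive rows, same chromosome, qualifying, same sign
  brk <- c(TRUE, windows$chrom[-1] != windows$chrom[-nrow(windows)] |
             sgn[-1] != sgn[-nrow(windows)] |
             !qual[-1] | !qual[-nrow(windows)])
  run_id <- cumsum(brk)
  calls <- windows |>
    mutate(run_id = run_id, qual = qual) |>
    filter(.data$qual) |>
    group_by(.data$run_id) |>
    summarise(
      # windows are sorted, so a run starts at its first row and ends at its last
      chrom = dplyr::first(.data$chrom), start = dplyr::first(.data$start),
      end = dplyr::last(.data$end),
      mean_log2 = mean(.data$log2_ratio), n_windows = n(), .groups = "drop"
    ) |>
    filter(.data$n_windows >= params$min_consecutive) |>
    mutate(
      cnv_type = ifelse(.data$mean_log2 > 0, "duplication", "deletion"),
      platform = "readdepth"
    ) |>
    select("chrom", "start", "end", "cnv_type", "mean_log2",
           "n_windows", "platform")
  attr(calls, "profile") <- windows |>
    select("chrom", "start", "end", "log2_ratio") |>
    mutate(skipped = skipped)
  class(calls) <- c("cnv_calls", class(calls))
  calls
}

#' Estimated copy number from a mean log2 ratio
#'
#' Against a diploid reference, copy number is `2 * 2^log2_ratio`.
#'
#' @param mean_log2 Mean log2 ratio of a CNV call.
#' @return Estimated copy number.
#' @export
estimate_copy_number <- function(mean_log2) 2 * 2^mean_log2

#' Compare CNV call sets across platforms
#'
#' Two CNVs overlap if they share at least 1 bp (half-open intervals, so a
#' shared boundary is not an overlap). CNVs of different platforms that
#' overlap -- directly or through a chain of overlaps -- form one
#' cross-platform region; the Venn counts report, per platform subset, the
#' number of such regions, and the consensus set keeps regions supported by
#' at least two platforms, merged as the union of their intervals.
#' Conflicting `cnv_type` within a consensus region is flagged, not
#' resolved.
#'
#' @param cnvs CNV tibble with `chrom`, `start`, `end`, `cnv_type` and a
#'   `platform` column holding >= 2 distinct platforms.
#' @return List of class `cnv_overlap`: `cnvs` (input with a `shared`
#'   flag), `venn` (tibble `platforms`, `n_regions`), `consensus` (merged
#'   regions with `platforms`, `n_platforms`, `type_conflict`).
#' @export
cnv_overlap_compare <- function(cnvs) {
  if (length(unique(cnvs$platform)) < 2) abort("need >= 2 platforms")
  n <- nrow(cnvs)
  pairs <- interval_overlap_pairs(cnvs, cnvs) |>
    filter(cnvs$platform[.data$i] != cnvs$platform[.data$j])
  shared <- seq_len(n) %in% pairs$i
  # connected components over all >=1 bp overlaps (any platform)
  all_pairs <- interval_overlap_pairs(cnvs, cnvs)
  comp <- seq_len(n)
  find <- function(x) {
    while (comp[x] != x) x <- comp[x]
    x
  }
  for (k in seq_len(nrow(all_pairs))) {
    a <- find(all_pairs$i[k])
    b <- find(all_pairs$j[k])
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  regions <- cnvs |>
    mutate(component = comp) |>
    group_by(.data$component) |>
    summarise(
      chrom = .data$chrom[1], start = min(.data$start), end = max(.data$end),
      platforms = paste(sort(unique(.data$platform)), collapse = "+"),
      n_platforms = length(unique(.data$platform)),
      type_conflict = length(unique(.data$cnv_type)) > 1,
      .groups = "drop"
    )
  venn <- regions |> count(.data$platforms, name = "n_regions")
  consensus <- regions |> filter(.data$n_platforms >= 2) |>
    select("chrom", "start", "end", "platforms", "n_platforms", "type_conflict")
  structure(
    list(cnvs = mutate(cnvs, shared = shared), venn = venn,
         consensus = consensus),
    class = "cnv_overlap"
  )
}

#' Summary statistics of a CNV set
#'
#' @param cnvs Interval tibble of CNVs.
#' @param layout Optional [genome_layout()] for the genome fraction.
#' @return One-row tibble: `n`, `total_bp`, `mean_length`, `min_length`,
#'   `max_length`, and `genome_fraction` when a layout is given. An empty
#'   set returns zeros with a warning.
#' @export
cnv_summary <- function(cnvs, layout = NULL) {
  if (nrow(cnvs) == 0) {
    warn("empty CNV set")
    out <- tibble(n = 0L, total_bp = 0, mean_length = 0,
                  min_length = 0, max_length = 0)
  } else {
    len <- cnvs$end - cnvs$start
    out <- tibble(n = nrow(cnvs), total_bp = sum(len), mean_length = mean(len),
                  min_length = min(len), max_length = max(len))
  }
  if (!is.null(layout)) out$genome_fraction <- out$total_bp / genome_size(layout)
  out
}

#' Filter structural variants by cross-assembly chromosome consistency
#'
#' An SV (inversion or translocation) with breakpoints at
#' `(chrom1, pos1)` and `(chrom2, pos2)` in assembly A is kept only if both
#' breakpoints can be located in assembly B *and* fall on the same B
#' chromosome as each other. Breakpoints absent from the position map cause
#' removal and are counted separately.
#'
#' @param svs Tibble with `sv_id`, `class`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2` (assembly A coordinates, 0-based).
#' @param position_map Tibble `chrom_a`, `pos_a`, `chrom_b`, `pos_b`
#'   mapping assembly A positions to assembly B (exact lookup).
#' @return List of class `cross_assembly_report`: `kept` (surviving svs),
#'   `report` (per class: `before`, `after`, `n_unmapped`), and
#'   `overall_reduction_pct`.
#' @export
cross_assembly_filter <- function(svs, position_map) {
  lookup <- function(chrom, pos) {
    idx <- match(paste(chrom, pos), paste(position_map$chrom_a, position_map$pos_a))
    position_map$chrom_b[idx]
  }
  b1 <- lookup(svs$chrom1, svs$pos1)
  b2 <- lookup(svs$chrom2, svs$pos2)
  unmapped <- is.na(b1) | is.na(b2)
  keep <- !unmapped & b1 == b2
  report <- svs |>
    mutate(keep = keep, unmapped = unmapped) |>
    group_by(.data$class) |>
    summarise(before = n(), after = sum(.data$keep),
              n_unmapped = sum(.data$unmapped), .groups = "drop")
  structure(
    list(
      kept = svs[keep, ],
      report = report,
      overall_reduction_pct = 100 * (1 - sum(keep) / nrow(svs))
    ),
    class = "cross_assembly_report"
  )
}

#' Permutation test of gene enrichment in CNV regions
#'
#' The observed statistic is the number of distinct genes overlapped (>= 1
#' bp) by any CNV. Under the null, each CNV keeps its length and is placed
#' uniformly at random: a chromosome able to hold it is drawn with
#' probability proportional to its length, then a start position uniformly.
#' Fold enrichment is observed over the null mean; the empirical p-value is
#' `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param cnvs Interval tibble of CNVs.
#' @param genes Interval tibble of genes.
#' @param layout A [genome_layout()]. Every CNV must fit on at least one
#'   chromosome.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional integer; when given, the permutation stream is
#'   seeded locally so results are bit-reproducible without touching the
#'   caller's RNG state.
#' @return List of class `perm_enrichment`: `observed`, `null_mean`,
#'   `fold`, `p_value`, `n_perm`, `null` (the null distribution).
#' @export
gene_enrichment_permutation <- function(cnvs, genes, layout, n_perm = 1000,
                                        seed = NULL) {
  if (n_perm < 100) abort("n_perm must be >= 100")
  check_chroms(cnvs$chrom, layout, "cnvs")
  widths <- cnvs$end - cnvs$start
  if (any(widths > max(layout$length))) {
    abort("a CNV is longer than every chromosome")
  }
  lev <- .chrom_levels(genes, layout[, "chrom", drop = FALSE], cnvs)
  unit <- max(layout$length) + 2 # null placements can reach chromosome ends
  gene_rng <- .ivl_ranges(genes, lev, unit)
  count_genes <- function(iv_df) {
    hits <- IRanges::overlapsAny(gene_rng, .ivl_ranges(iv_df, lev, unit))
    sum(hits)
  }
  observed <- count_genes(cnvs)
  draw_null <- function() {
    null <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      chrom <- character(length(widths))
      start <- numeric(length(widths))
      for (k in seq_along(widths)) {
        ok <- layout$length >= widths[k]
        ci <- sample(which(ok), 1, prob = layout$length[ok])
        chrom[k] <- layout$chrom[ci]
        start[k] <- floor(runif(1, 0, layout$length[ci] - widths[k] + 1))
      }
      null[p] <- count_genes(tibble(chrom = chrom, start = start,
                                    end = start + widths))
    }
    null
  }
  null <- if (is.null(seed)) draw_null() else withr::with_seed(seed, draw_null())
  structure(
    list(observed = observed, null_mean = mean(null),
         fold = observed / mean(null),
         p_value = (1 + sum(null >= observed)) / (n_perm + 1),
         n_perm = n_perm, null = null),
    class = "perm_enrichment"
  )
}

#' Confirmation rate of CNV validation assays
#'
#' Assay failures (e.g. primers that did not work) are excluded from the
#' denominator: the rate is `confirmed / (tested - failed)`.
#'
#' @param outcomes Character vector (or factor) with values `confirmed`,
#'   `not_confirmed`, `assay_failed`.
#' @return One-row tibble: `n_tested`, `n_failed`, `n_confirmed`,
#'   `confirmation_rate` (NA with a warning if every assay failed).
#' @examples
#' validation_rate(rep(c("confirmed", "not_confirmed", "assay_failed"),
#'                     c(19, 3, 6)))
#' @export
validation_rate <- function(outcomes) {
  outcomes <- as.character(outcomes)
  bad <- setdiff(unique(outcomes), c("confirmed", "not_confirmed", "assay_failed"))
  if (length(bad) > 0) abort(paste0("unknown outcome label(s): ", paste(bad, collapse = ", ")))
  n <- length(outcomes)
  nf <- sum(outcomes == "assay_failed")
  nc <- sum(outcomes == "confirmed")
  rate <- if (n - nf == 0) {
    warn("all assays failed; confirmation rate undefined")
    NA_real_
  } else {
    nc / (n - nf)
  }
  tibble(n_tested = n, n_failed = nf, n_confirmed = nc,
         confirmation_rate = rate)
}
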