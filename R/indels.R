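#' Intersect two left-normalized indel call sets
#'
#' Keeps indels called identically -- same `(chrom, pos, ref, alt)` after
#' left normalization -- by both callers, the standard way of suppressing
#' the high indel false-positive rate of any single caller.
#'
#' @param set_a,set_b Indel call tibbles, both already left-normalized
#'   (see [normalize_indels()]).
#' @return The rows of `set_a` whose key appears in `set_b`.
#' @export
intersect_indel_callers <- function(set_a, set_b) {
  semi_join(set_a, set_b, by = c("chrom", "pos", "ref", "alt"))
}

#' Parameters of the post-hoc indel filter
#'
#' The six post-filter criteria for intersected intra-read indels: support
#' on both strands, minimum base quality, a read-depth window, and no
#' overlap with assembly N runs. The mapping-quality downgrade coefficient
#' is a caller-time setting and is recorded as upstream metadata only -- it
#' cannot be re-applied post hoc.
#'
#' @param min_base_quality Minimum base quality (default 20).
#' @param min_depth,max_depth Read-depth window (defaults 4 and 30).
#' @param require_both_strands Require >= 1 supporting read per strand.
#' @param exclude_n_overlap Drop indels overlapping the N mask.
#' @return A list of class `indel_filter_params`.
#' @export
indel_filter_params <- function(min_base_quality = 20, min_depth = 4,
                                max_depth = 30, require_both_strands = TRUE,
                                exclude_n_overlap = TRUE) {
  if (min_depth > max_depth) abort("min_depth must be <= max_depth")
  structure(
    list(min_base_quality = min_base_quality, min_depth = min_depth,
         max_depth = max_depth, require_both_strands = require_both_strands,
         exclude_n_overlap = exclude_n_overlap,
         upstream = "mapping-quality downgrade coefficient 50 applied at call time"),
    class = "indel_filter_params"
  )
}

#' Apply the post-hoc indel filter
#'
#' @param indels Indel tibble annotated with `fwd_support`, `rev_support`,
#'   `base_quality` and `depth`. Indels missing any required annotation are
#'   dropped and counted in the `n_missing_annotation` attribute.
#' @param params An [indel_filter_params()].
#' @param n_mask Optional interval tibble of assembly N runs.
#' @return The surviving indels; attributes `n_missing_annotation` and
#'   `n_removed` record the bookkeeping. The filter is idempotent.
#' @export
filter_indels <- function(indels, params = indel_filter_params(),
                          n_mask = NULL) {
  need <- c("fwd_support", "rev_support", "base_quality", "depth")
  miss_col <- setdiff(need, names(indels))
  if (length(miss_col) > 0) {
    abort(paste0("indels lack annotation column(s): ", paste(miss_col, collapse = ", ")))
  }
  incomplete <- !stats::complete.cases(indels[, need])
  kept <- indels[!incomplete, ]
  ok <- rep(TRUE, nrow(kept))
  if (params$require_both_strands) {
    ok <- ok & kept$fwd_support >= 1 & kept$rev_support >= 1
  }
  ok <- ok & kept$base_quality >= params$min_base_quality
  ok <- ok & kept$depth >= params$min_depth & kept$depth <= params$max_depth
  if (params$exclude_n_overlap && !is.null(n_mask) && nrow(n_mask) > 0) {
    span <- pmax(1, nchar(kept$ref) - 1)
    iv <- tibble(chrom = kept$chrom, start = kept$pos, end = kept$pos + span)
    ok <- ok & count_overlaps_ivl(iv, n_mask) == 0
  }
  out <- kept[ok, ]
  attr(out, "n_missing_annotation") <- sum(incomplete)
  attr(out, "n_removed") <- nrow(indels) - nrow(out)
  out
}

#' Indel size in bp
#'
#' @param indels Indel tibble with `ref`, `alt`.
#' @return `abs(nchar(alt) - nchar(ref))`.
#' @export
indel_size <- function(indels) abs(nchar(indels$alt) - nchar(indels$ref))

#' Frame-preserving (3n) classification of coding indels
#'
#' Coding indels are expected to be enriched for sizes that are multiples
#' of three, because frameshifts are removed by purifying selection. Tests
#' the 2x2 table (coding vs genome-wide) x (3n vs non-3n) with a plain
#' chi-square (1 df, no continuity correction by default).
#'
#' @param coding_sizes,background_sizes Integer vectors of indel sizes
#'   (>= 1 bp).
#' @param correct Apply Yates continuity correction.
#' @return List of class `threen_test`: `table` (2x2 counts), `statistic`,
#'   `p_value`, and per-group 3n fractions.
#' @export
classify_3n <- function(coding_sizes, background_sizes, correct = FALSE) {
  if (length(coding_sizes) == 0 || length(background_sizes) == 0) {
    abort("both size vectors must be non-empty")
  }
  if (any(c(coding_sizes, background_sizes) < 1)) abort("indel sizes must be >= 1")
  tab <- rbind(
    coding = c(`3n` = sum(coding_sizes %% 3 == 0),
               non_3n = sum(coding_sizes %% 3 != 0)),
    background = c(sum(background_sizes %% 3 == 0),
                   sum(background_sizes %% 3 != 0))
  )
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(
    list(table = tab, statistic = unname(ct$statistic),
         p_value = ct$p.value,
         frac_3n_coding = tab[1, 1] / sum(tab[1, ]),
         frac_3n_background = tab[2, 1] / sum(tab[2, ])),
    class = "threen_test"
  )
}

#' Relative protein position of a coding indel
#'
#' The position of the first affected codon divided by the protein length,
#' in (0, 1]. CDS coordinates are walked strand-aware, so the first codon
#' of a minus-strand gene lies at the right end of its CDS span.
#'
#' @param pos 0-based genomic position of the indel (first affected base).
#' @param gene Gene model: tibble with one row per CDS interval, columns
#'   `chrom`, `start`, `end` (0-based half-open), `strand` (`"+"`/`"-"`).
#'   Total CDS length must be divisible by 3; protein length is CDS
#'   length/3 - 1 (stop codon excluded).
#' @return Fraction in (0, 1].
#' @export
relative_protein_position <- function(pos, gene) {
  gene <- arrange(gene, .data$start)
  cds_len <- sum(gene$end - gene$start)
  if (cds_len %% 3 != 0) abort("CDS length must be divisible by 3")
  protein_length <- cds_len / 3 - 1
  hit <- which(pos >= gene$start & pos < gene$end)
  if (length(hit) == 0) abort("position is outside the CDS")
  strand <- gene$strand[1]
  if (strand == "+") {
    before <- sum(pmax(0, pmin(gene$end, pos) - gene$start))
  } else {
    before <- sum(pmax(0, gene$end - pmax(gene$start, pos + 1)))
  }
  codon <- floor(before / 3) + 1
  codon <- min(codon, protein_length) # indel in the stop codon maps to last residue
  codon / protein_length
}

#' SNP-to-indel ratio
#'
#' @param n_snp,n_indel Counts; `n_indel` must be > 0.
#' @return `n_snp / n_indel`.
#' @export
snp_indel_ratio <- function(n_snp, n_indel) {
  if (n_indel <= 0) abort("n_indel must be > 0")
  n_snp / n_indel
}
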