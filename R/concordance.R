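#' Partition SNP sites by the subset of callers reporting them
#'
#' Every site in the union of the call sets is assigned to exactly one
#' non-empty caller subset (the Venn partition). Site identity is
#' `(chrom, pos)`; allele agreement is evaluated separately by the
#' concordance functions. Besides the overall partition, per-zygosity
#' partitions are computed in which a caller is counted at a site only if
#' it called that site with the given zygosity.
#'
#' @param calls A call tibble holding SNPs from two or more callers
#'   (distinguished by the `caller` column). A caller reporting the same
#'   site twice is an error.
#' @return A tibble of class `venn_partition` with columns `zygosity`
#'   (`"all"`, `"het"`, `"hom"`), `callers` (subset id, caller names joined
#'   by `+` in alphabetical order) and `n`. Within each zygosity stratum the
#'   subset counts sum to the size of that stratum's union.
#' @examples
#' calls <- tibble::tibble(
#'   chrom = "chr1", pos = c(1, 2, 1), vtype = "snp",
#'   zygosity = c("het", "hom_alt", "het"), caller = c("a", "a", "b")
#' )
#' venn_partition(calls)
#' @export
venn_partition <- function(calls) {
  calls <- filter(calls, .data$vtype == "snp")
  if (length(unique(calls$caller)) < 2) abort("need SNP calls from >= 2 callers")
  if (anyDuplicated(calls[, c("caller", "chrom", "pos")]) > 0) {
    abort("a caller reports duplicate site keys")
  }
  one_partition <- function(df, tag) {
    if (nrow(df) == 0) {
      return(tibble(zygosity = character(), callers = character(), n = integer()))
    }
    df |>
      group_by(.data$chrom, .data$pos) |>
      summarise(callers = paste(sort(unique(.data$caller)), collapse = "+"),
                .groups = "drop") |>
      count(.data$callers, name = "n") |>
      mutate(zygosity = tag, .before = 1)
  }
  out <- bind_rows(
    one_partition(calls, "all"),
    one_partition(filter(calls, .data$zygosity == "het"), "het"),
    one_partition(filter(calls, .data$zygosity == "hom_alt"), "hom")
  )
  class(out) <- c("venn_partition", class(out))
  out
}

#' Fraction of union sites shared by all callers
#'
#' @param n_intersection Sites called by every pipeline.
#' @param n_union Sites called by at least one pipeline.
#' @return `n_intersection / n_union`.
#' @examples
#' intersection_fraction(2859650, 6239482) # ~0.458
#' @export
intersection_fraction <- function(n_intersection, n_union) {
  if (n_union <= 0) abort("n_union must be > 0")
  n_intersection / n_union
}

#' Classify one chip site against the sequencing call at the same position
#'
#' Category semantics, applied in order: the sequencing pipeline reported an
#' indel at the site -> `as_indel`; chip het vs sequencing hom ->
#' `het_to_hom`; chip hom vs sequencing het -> `hom_to_het`; same zygosity
#' with identical unordered allele sets -> `consistent`, otherwise
#' `inconsistent`; no sequencing record -> `not_detected`. Chip no-calls
#' must be excluded upstream.
#'
#' @param chip_call Canonical chip call string, e.g. `"A/G"`.
#' @param seq_zygosity,seq_ref,seq_alt,seq_vtype The sequencing call at the
#'   site, or `NA`s if absent.
#' @return One of `consistent`, `het_to_hom`, `hom_to_het`, `as_indel`,
#'   `inconsistent`, `not_detected`.
#' @export
classify_site <- function(chip_call, seq_zygosity, seq_ref, seq_alt, seq_vtype) {
  if (is.na(chip_call)) abort("chip no-call reached classify_site; exclude upstream")
  if (is.na(seq_zygosity)) return("not_detected")
  if (!is.na(seq_vtype) && seq_vtype != "snp") return("as_indel")
  chip_al <- strsplit(chip_call, "/", fixed = TRUE)[[1]]
  chip_het <- chip_al[1] != chip_al[2]
  seq_het <- seq_zygosity == "het"
  if (chip_het && !seq_het) return("het_to_hom")
  if (!chip_het && seq_het) return("hom_to_het")
  seq_al <- if (seq_het) c(seq_ref, seq_alt) else
    if (seq_zygosity == "hom_alt") c(seq_alt, seq_alt) else c(seq_ref, seq_ref)
  if (setequal(sort(chip_al), sort(seq_al)) &&
      identical(sort(chip_al), sort(seq_al))) {
    return("consistent")
  }
  "inconsistent"
}

#' Classify every chip marker against a sequencing call set
#'
#' Joins chip markers to one caller's calls by `(chrom, pos)` and applies
#' [classify_site()] at each marker.
#'
#' @param chip Chip genotype tibble; no-calls are dropped.
#' @param calls Call tibble of a single caller.
#' @return The chip tibble with a `category` column and a `chip_zygosity`
#'   column (`het`/`hom`).
#' @export
classify_concordance <- function(chip, calls) {
  chip <- filter(chip, !is.na(.data$call))
  if (length(unique(calls$caller)) > 1) abort("calls must come from a single caller")
  joined <- left_join(
    chip,
    calls |> select("chrom", "pos", seq_ref = "ref", seq_alt = "alt",
                    seq_zygosity = "zygosity", seq_vtype = "vtype"),
    by = c("chrom", "pos")
  )
  al <- strsplit(joined$call, "/", fixed = TRUE)
  joined$chip_zygosity <- ifelse(
    vapply(al, function(x) x[1] != x[2], logical(1)), "het", "hom"
  )
  joined$category <- purrr::pmap_chr(
    joined[, c("call", "seq_zygosity", "seq_ref", "seq_alt", "seq_vtype")],
    function(call, seq_zygosity, seq_ref, seq_alt, seq_vtype) {
      classify_site(call, seq_zygosity, seq_ref, seq_alt, seq_vtype)
    }
  )
  joined
}

#' Summarise concordance categories, split by chip zygosity
#'
#' Percentages are computed over *detected* sites (the `not_detected`
#' category is excluded from the denominator, as in a comparison table whose
#' rows sum to the detected chip SNPs). The detection rate -- the fraction
#' of chip SNPs also discovered by sequencing -- is reported separately.
#'
#' @param classified Output of [classify_concordance()].
#' @return Tibble of class `concordance_summary` with `chip_zygosity`,
#'   `category`, `n`, `pct` (NA for `not_detected`), plus attributes
#'   `detection_rate` and `n_total`.
#' @export
concordance_summary <- function(classified) {
  if (nrow(classified) == 0) abort("no classified sites")
  out <- classified |>
    count(.data$chip_zygosity, .data$category, name = "n") |>
    group_by(.data$chip_zygosity) |>
    mutate(pct = ifelse(
      .data$category == "not_detected", NA_real_,
      100 * .data$n / sum(.data$n[.data$category != "not_detected"])
    )) |>
    ungroup()
  if (all(classified$category == "not_detected")) {
    warn("zero detected sites; fractions undefined")
  }
  attr(out, "detection_rate") <- mean(classified$category != "not_detected")
  attr(out, "n_total") <- nrow(classified)
  class(out) <- c("concordance_summary", class(out))
  out
}

#' Concordance percentages from a table of category counts
#'
#' Convenience for worked examples where only per-pipeline category counts
#' are available: each percentage uses the row total of detected sites as
#' denominator.
#'
#' @param counts Tibble with a `pipeline` column and one column per
#'   category count (e.g. `consistent`, `het_to_hom`, `as_indel`,
#'   `inconsistent`).
#' @return `counts` with a matching `pct_<category>` column per category.
#' @examples
#' concordance_rates(tibble::tibble(
#'   pipeline = "bwa", consistent = 167758, het_to_hom = 10590,
#'   as_indel = 30, inconsistent = 477
#' ))$pct_consistent # 93.8
#' @export
concordance_rates <- function(counts) {
  cat_cols <- setdiff(names(counts), "pipeline")
  tot <- rowSums(counts[cat_cols])
  for (cc in cat_cols) {
    counts[[paste0("pct_", cc)]] <- 100 * counts[[cc]] / tot
  }
  counts
}

#' Estimate the per-base, per-generation mutation rate from new
#' heterozygotes in an IBD region
#'
#' Inside a recent identity-by-descent segment every heterozygote verified
#' by independent platforms is a candidate de-novo mutation. With `n_new`
#' such sites observed at a heterozygote detection rate `det`, over `g`
#' generations on a `ploidy`-stranded region of `L` bp, the rate is
#' `n_new / (det * ploidy * g * L)`.
#'
#' @param n_new_het Verified new heterozygous sites (>= 0).
#' @param het_detection_rate Probability a true heterozygote is detected by
#'   the verifying platform, in (0, 1].
#' @param ploidy Number of chromosome copies mutations can arise on (2 for
#'   an autosomal region).
#' @param generations Generations separating the two IBD copies from the
#'   common ancestor.
#' @param region_length IBD region length in bp.
#' @return Mutation rate per bp per generation.
#' @examples
#' mutation_rate_estimate(1, 0.09, 2, 3, 9e7) # ~2e-8
#' @export
mutation_rate_estimate <- function(n_new_het, het_detection_rate, ploidy,
                                   generations, region_length) {
  if (n_new_het < 0) abort("n_new_het must be >= 0")
  if (het_detection_rate <= 0 || region_length <= 0 || ploidy <= 0 ||
      generations <= 0) {
    abort("detection rate, ploidy, generations and length must be > 0")
  }
  n_new_het / (het_detection_rate * ploidy * generations * region_length)
}
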