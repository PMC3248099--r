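#' Error profile of a simulated variant caller
#'
#' Encodes the two error processes that dominate real multi-caller
#' disagreement: misalignment-driven false heterozygotes (concentrated in
#' CNV duplications, with low minimum allele percentage) and
#' depth-dependent under-calling of true heterozygotes (a heterozygote
#' sampled by reads of only one allele is reported as homozygous).
#'
#' @param base_fp_het_rate False-heterozygote rate per bp outside
#'   duplications.
#' @param dup_fp_multiplier Multiplier on the FP rate inside CNV
#'   duplications.
#' @param het_undercall If `TRUE`, allele depths of true heterozygotes are
#'   binomially sampled from the read depth, so low-depth sites lose one
#'   allele and are emitted as homozygous (or dropped when the alternate
#'   allele is unsampled). If `FALSE`, allele depths are split evenly and
#'   every true variant is emitted faithfully.
#' @param fp_vaf_shape Beta shape parameters of the variant-allele fraction
#'   of false heterozygotes (low-MAP by default).
#' @param tp_vaf_shape Optional Beta shape parameters for true-heterozygote
#'   allele fractions; `NULL` keeps the unbiased 0.5 binomial.
#' @param min_depth Floor on simulated read depth at true variant sites.
#' @return A list of class `caller_profile`.
#' @export
caller_profile <- function(base_fp_het_rate = 0, dup_fp_multiplier = 1,
                           het_undercall = TRUE, fp_vaf_shape = c(1, 6),
                           tp_vaf_shape = NULL, min_depth = 1) {
  structure(
    list(base_fp_het_rate = base_fp_het_rate,
         dup_fp_multiplier = dup_fp_multiplier,
         het_undercall = het_undercall,
         fp_vaf_shape = fp_vaf_shape,
         tp_vaf_shape = tp_vaf_shape,
         min_depth = min_depth),
    class = "caller_profile"
  )
}

#' Default four-caller profiles
#'
#' Two mapping-quality-aware pipelines with low false-heterozygote rates
#' and two pipelines without mapping-quality filtering whose FP rates are
#' roughly nine-fold higher and more strongly concentrated in
#' duplications -- the contrast observed between Bayesian pipelines with
#' and without alignment-quality models.
#'
#' @return Named list of [caller_profile()]s.
#' @export
default_caller_profiles <- function() {
  list(
    bwa = caller_profile(base_fp_het_rate = 1.3e-5, dup_fp_multiplier = 5),
    smalt = caller_profile(base_fp_het_rate = 1.4e-5, dup_fp_multiplier = 5),
    clc = caller_profile(base_fp_het_rate = 1.2e-4, dup_fp_multiplier = 10),
    giga = caller_profile(base_fp_het_rate = 1.2e-4, dup_fp_multiplier = 10)
  )
}

#' Configuration of the synthetic diploid genome
#'
#' Defines a small diploid genome (three autosomes plus a haploid X,
#' ~12 Mb) with planted truth: SNPs and indels with known zygosity, one
#' large IBD region that is homozygous by construction, CNVs with known
#' copy number, gene intervals, per-caller call sets with configurable
#' error processes, two-chip genotypes with a per-site error rate, and
#' negative-binomial (Poisson-Gamma overdispersed) window read counts for
#' a test/reference sample pair.
#'
#' @param layout Genome layout; default 3 autosomes + X totaling 12 Mb.
#' @param snp_density,indel_density True variants per bp (defaults one SNP
#'   per 2 kb and a genome-wide SNP:indel ratio of 15:1).
#' @param het_fraction Fraction of true variants that are heterozygous
#'   outside IBD regions (autosomes).
#' @param ibd Interval tibble of planted IBD regions (all truth homozygous
#'   inside).
#' @param cnv Tibble `chrom`, `start`, `end`, `copy_number` with copy
#'   numbers in {0, 1, 3, 4}; overlapping CNVs are an error.
#' @param gene_density Genes per bp; `gene_length` their fixed length.
#' @param gene_length Gene length in bp.
#' @param caller_profiles Named list of [caller_profile()]s (may be empty).
#' @param chip_error_rate Per-genotype flip probability on each chip.
#' @param chip_marker_density Array markers per bp of genome (markers are
#'   drawn from true SNP sites; the SNP50 chip uses half of the HD markers
#'   so the two chips share markers).
#' @param coverage_mean,coverage_overdispersion Negative-binomial mean and
#'   size of per-site read depth (halved on the haploid X); `Inf` size
#'   gives plain Poisson.
#' @param window_size,window_reads_mean,window_overdispersion Window grid
#'   and negative-binomial count model for the read-depth CNV input; the
#'   test sample's window mean is scaled by copy number over the diploid
#'   baseline (CN/2), the reference sample is diploid everywhere.
#' @param seed Mandatory integer seed; all simulation randomness is local
#'   to this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(layout = genome_layout(
                         c("chr1", "chr2", "chr3", "chrX"),
                         c(4e6, 3.5e6, 3e6, 1.5e6), sex_chroms = "chrX"
                       ),
                       snp_density = 5e-4,
                       indel_density = 5e-4 / 15,
                       het_fraction = 0.5,
                       ibd = tibble(chrom = "chr1", start = 5e5, end = 3.5e6),
                       cnv = tibble(
                         chrom = c("chr2", "chr2", "chr3", "chr3"),
                         start = c(1.2e6, 2.4e6, 0.8e6, 2.0e6),
                         end = c(1.32e6, 2.5e6, 0.88e6, 2.1e6),
                         copy_number = c(4, 1, 3, 0)
                       ),
                       gene_density = 2.5e-5,
                       gene_length = 5e3,
                       caller_profiles = default_caller_profiles(),
                       chip_error_rate = 5.52e-4,
                       chip_marker_density = 1 / 3000,
                       coverage_mean = 15,
                       coverage_overdispersion = 8,
                       window_size = 1e4,
                       window_reads_mean = 300,
                       window_overdispersion = 500,
                       seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (snp_density <= 0 || indel_density <= 0) abort("densities must be > 0")
  if (!all(cnv$copy_number %in% c(0, 1, 3, 4))) {
    abort("copy numbers must be in {0, 1, 3, 4}")
  }
  if (nrow(cnv) > 1) {
    ov <- interval_overlap_pairs(cnv, cnv) |> filter(.data$i != .data$j)
    if (nrow(ov) > 0) abort("overlapping CNVs in cnv spec")
  }
  structure(
    list(layout = layout, snp_density = snp_density,
         indel_density = indel_density, het_fraction = het_fraction,
         ibd = ibd, cnv = cnv, gene_density = gene_density,
         gene_length = gene_length, caller_profiles = caller_profiles,
         chip_error_rate = chip_error_rate,
         chip_marker_density = chip_marker_density,
         coverage_mean = coverage_mean,
         coverage_overdispersion = coverage_overdispersion,
         window_size = window_size, window_reads_mean = window_reads_mean,
         window_overdispersion = window_overdispersion,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

rnb <- function(n, mu, size) {
  if (is.infinite(size)) rpois(n, mu) else rnbinom(n, mu = mu, size = size)
}

BASES <- c("A", "C", "G", "T")

#' Simulate a diploid genome with planted truth
#'
#' Deterministic given `config$seed` (the caller's RNG state is untouched).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_result` with elements `truth` (list:
#'   `variants`, `ibd`, `cnv`, `genes`, `caller_errors`), `calls` (all
#'   emitted caller calls, `caller` column), `chip` (HD + SNP50 genotypes,
#'   `chip` column), `window_counts`, `layout`, `config`.
#' @export
simulate_genome <- function(config) {
  withr::with_seed(config$seed, simulate_impl(config))
}

simulate_impl <- function(config) {
  layout <- config$layout
  dup_regions <- config$cnv[config$cnv$copy_number > 2, , drop = FALSE]

  draw_variants <- function(density, indel = FALSE) {
    purrr::map(seq_len(nrow(layout)), function(i) {
      len <- layout$length[i]
      n <- rpois(1, len * density)
      if (n == 0) return(NULL)
      pos <- sort(sample.int(len - 20, n)) - 1 + 10
      ref <- sample(BASES, n, replace = TRUE)
      if (indel) {
        size <- pmin(12, 1 + rpois(n, 1.5))
        is_del <- runif(n) < 0.5
        seg <- vapply(size, function(s) paste(sample(BASES, s, replace = TRUE),
                                              collapse = ""), character(1))
        alt <- ifelse(is_del, ref, paste0(ref, seg))
        ref <- ifelse(is_del, paste0(ref, seg), ref)
      } else {
        alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
      }
      tibble(chrom = layout$chrom[i], pos = pos, ref = ref, alt = alt)
    }) |> purrr::list_rbind()
  }

  snps <- draw_variants(config$snp_density)
  indels <- draw_variants(config$indel_density, indel = TRUE)
  variants <- bind_rows(snps, indels) |>
    mutate(vtype = variant_type(.data$ref, .data$alt)) |>
    arrange(.data$chrom, .data$pos)
  # drop colliding positions so site keys are unique
  variants <- variants[!duplicated(variants[, c("chrom", "pos")]), ]

  on_sex <- variants$chrom %in% layout$chrom[layout$sex]
  in_ibd <- in_intervals(variants$chrom, variants$pos, config$ibd)
  variants$zygosity <- ifelse(
    on_sex | in_ibd, "hom_alt",
    ifelse(runif(nrow(variants)) < config$het_fraction, "het", "hom_alt")
  )

  genes <- purrr::map(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    n <- round(len * config$gene_density)
    if (n == 0) return(NULL)
    start <- sort(sample.int(len - config$gene_length, n)) - 1
    tibble(chrom = layout$chrom[i], start = start,
           end = start + config$gene_length,
           label = paste0(layout$chrom[i], "_g", seq_len(n)))
  }) |> purrr::list_rbind()

  # ---- caller call sets -------------------------------------------------
  calls <- list()
  errors <- list()
  for (cname in names(config$caller_profiles)) {
    pr <- config$caller_profiles[[cname]]
    mu <- ifelse(on_sex, config$coverage_mean / 2, config$coverage_mean)
    depth <- pmax(pr$min_depth,
                  rnb(nrow(variants), mu, config$coverage_overdispersion))
    v <- variants
    v$depth <- depth
    is_het <- v$zygosity == "het"
    if (pr$het_undercall) {
      p_alt <- if (is.null(pr$tp_vaf_shape)) 0.5 else
        rbeta(sum(is_het), pr$tp_vaf_shape[1], pr$tp_vaf_shape[2])
      ad_alt <- rbinom(sum(is_het), depth[is_het], p_alt)
    } else {
      ad_alt <- ceiling(depth[is_het] / 2)
    }
    v$ad_alt <- ifelse(is_het, NA_real_, v$depth)
    v$ad_alt[is_het] <- ad_alt
    v$ad_ref <- v$depth - v$ad_alt
    # under-calling: het with no sampled alt allele vanishes, with no
    # sampled ref allele it is emitted as hom_alt
    dropped <- is_het & v$ad_alt == 0
    to_hom <- is_het & v$ad_ref == 0 & v$ad_alt > 0
    v$zygosity[to_hom] <- "hom_alt"
    emitted <- v[!dropped, ]

    # false heterozygotes
    fp <- purrr::map(seq_len(nrow(layout)), function(i) {
      chr <- layout$chrom[i]
      len <- layout$length[i]
      dups <- dup_regions[dup_regions$chrom == chr, , drop = FALSE]
      dup_bp <- sum(dups$end - dups$start)
      n_bg <- rpois(1, (len - dup_bp) * pr$base_fp_het_rate)
      n_dup <- if (dup_bp > 0) {
        rpois(1, dup_bp * pr$base_fp_het_rate * pr$dup_fp_multiplier)
      } else 0
      if (n_bg + n_dup == 0) return(NULL)
      pos_bg <- if (n_bg > 0) sample.int(len, n_bg) - 1 else integer(0)
      pos_dup <- if (n_dup > 0) {
        off <- sample.int(dup_bp, n_dup) - 1
        cum <- cumsum(dups$end - dups$start)
        k <- findInterval(off, c(0, head(cum, -1) + 0)) # which dup
        k <- pmin(pmax(k, 1), nrow(dups))
        dups$start[k] + (off - c(0, head(cum, -1))[k])
      } else numeric(0)
      tibble(chrom = chr, pos = c(pos_bg, pos_dup))
    }) |> purrr::list_rbind()
    if (!is.null(fp) && nrow(fp) > 0) {
      fp <- fp[!duplicated(fp[, c("chrom", "pos")]), ]
      fp <- anti_join(fp, variants[, c("chrom", "pos")], by = c("chrom", "pos"))
      nf <- nrow(fp)
      fp$ref <- sample(BASES, nf, replace = TRUE)
      fp$alt <- vapply(fp$ref, function(r) sample(setdiff(BASES, r), 1), character(1))
      fp$vtype <- "snp"
      fp$zygosity <- "het"
      fp$depth <- pmax(2, rnb(nf, config$coverage_mean,
                              config$coverage_overdispersion))
      vaf <- rbeta(nf, pr$fp_vaf_shape[1], pr$fp_vaf_shape[2])
      fp$ad_alt <- pmax(1, round(vaf * fp$depth))
      fp$ad_ref <- fp$depth - fp$ad_alt
    } else {
      fp <- NULL
    }

    cl <- bind_rows(emitted, fp) |>
      mutate(caller = cname) |>
      arrange(.data$chrom, .data$pos) |>
      select("chrom", "pos", "ref", "alt", "vtype", "zygosity",
             "depth", "ad_ref", "ad_alt", "caller")
    calls[[cname]] <- cl
    errors[[cname]] <- bind_rows(
      if (any(dropped)) tibble(caller = cname, type = "undercall_dropped",
                               chrom = v$chrom[dropped], pos = v$pos[dropped]),
      if (any(to_hom)) tibble(caller = cname, type = "undercall_hom",
                              chrom = v$chrom[to_hom], pos = v$pos[to_hom]),
      if (!is.null(fp)) tibble(caller = cname, type = "fp_het",
                               chrom = fp$chrom, pos = fp$pos)
    )
  }

  # ---- chip genotypes ---------------------------------------------------
  snp_truth <- variants[variants$vtype == "snp", ]
  n_hd <- min(nrow(snp_truth),
              round(genome_size(layout) * config$chip_marker_density))
  hd_idx <- sort(sample.int(nrow(snp_truth), n_hd))
  snp50_idx <- sort(sample(hd_idx, floor(n_hd / 2)))
  make_chip <- function(idx, chip_name) {
    m <- snp_truth[idx, ]
    call <- ifelse(m$zygosity == "het",
                   paste(pmin(m$ref, m$alt), pmax(m$ref, m$alt), sep = "/"),
                   paste(m$alt, m$alt, sep = "/"))
    flip <- runif(nrow(m)) < config$chip_error_rate
    call[flip] <- ifelse(
      m$zygosity[flip] == "het",
      paste(m$alt[flip], m$alt[flip], sep = "/"), # het mistyped as hom
      paste(pmin(m$ref[flip], m$alt[flip]),
            pmax(m$ref[flip], m$alt[flip]), sep = "/") # hom mistyped as het
    )
    tibble(marker_id = paste0("m", match(idx, hd_idx)),
           chrom = m$chrom, pos = m$pos,
           allele_a = pmin(m$ref, m$alt), allele_b = pmax(m$ref, m$alt),
           call = call, chip = chip_name,
           flipped = flip)
  }
  chip <- bind_rows(make_chip(hd_idx, "HD"), make_chip(snp50_idx, "SNP50"))

  # ---- window read counts ----------------------------------------------
  grid <- tile_genome(layout, config$window_size)
  on_sex_w <- grid$chrom %in% layout$chrom[layout$sex]
  base_mu <- ifelse(on_sex_w, config$window_reads_mean / 2,
                    config$window_reads_mean) *
    (grid$end - grid$start) / config$window_size
  cn <- rep(2, nrow(grid))
  for (k in seq_len(nrow(config$cnv))) {
    hit <- grid$chrom == config$cnv$chrom[k] &
      grid$start >= config$cnv$start[k] & grid$end <= config$cnv$end[k]
    cn[hit] <- config$cnv$copy_number[k]
  }
  grid$count_test <- rnb(nrow(grid), base_mu * cn / 2, config$window_overdispersion)
  grid$count_ref <- rnb(nrow(grid), base_mu, config$window_overdispersion)

  structure(
    list(
      truth = list(
        variants = variants, ibd = config$ibd, cnv = config$cnv,
        genes = genes, caller_errors = purrr::list_rbind(errors)
      ),
      calls = purrr::list_rbind(calls),
      chip = chip,
      window_counts = grid,
      layout = layout,
      config = config
    ),
    class = "sim_result"
  )
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits one VCF per caller, the chip genotype TSV, the window-count TSV,
#' truth BEDs (IBD, CNV, genes), a truth variant TSV, the genome layout and
#' a YAML record of the scalar configuration. Output is byte-identical for
#' the same simulation.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cname in unique(sim$calls$caller)) {
    write_vcf(sim$calls[sim$calls$caller == cname, ],
              file.path(dir, paste0(cname, ".vcf")))
  }
  write_chip_genotypes(sim$chip |> select(-"flipped"),
                       file.path(dir, "chip.tsv"))
  readr::write_tsv(sim$window_counts, file.path(dir, "windows.tsv"))
  write_bed(sim$truth$ibd |> mutate(label = "IBD"),
            file.path(dir, "truth_ibd.bed"))
  write_bed(sim$truth$cnv |> mutate(label = paste0("CN", .data$copy_number)),
            file.path(dir, "truth_cnv.bed"))
  write_bed(sim$truth$genes, file.path(dir, "truth_genes.bed"))
  readr::write_tsv(sim$truth$variants, file.path(dir, "truth_variants.tsv"))
  write_genome_layout(sim$layout, file.path(dir, "layout.tsv"))
  cfg <- sim$config
  scalars <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) <= 2, logical(1))]
  yaml::write_yaml(scalars, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Ready-made simulation profiles
#'
#' * `clean` -- every error process off: caller calls equal the truth
#'   exactly, chip genotypes are error-free.
#' * `paperlike` -- four callers with the contrast between mapping-quality
#'   aware and unaware pipelines, duplication-concentrated false
#'   heterozygotes, depth-dependent under-calling, chip errors at the
#'   deduced two-chip error rate.
#' * `adversarial` -- misalignment-heavy callers: false heterozygotes at
#'   high rate with variant-allele fractions ~ Beta(1, 6) and true
#'   heterozygotes ~ Beta(10, 10), the regime the post-hoc heterozygote
#'   filter is designed for.
#'
#' @param profile One of `"clean"`, `"paperlike"`, `"adversarial"`.
#' @param seed Simulation seed.
#' @param dir Optional directory; when given the bundle is also written
#'   with [write_sim_bundle()].
#' @return A `sim_result`.
#' @export
end_to_end_fixture <- function(profile = c("clean", "paperlike", "adversarial"),
                               seed = 42L, dir = NULL) {
  profile <- match.arg(profile)
  config <- switch(
    profile,
    clean = sim_config(
      caller_profiles = lapply(default_caller_profiles(), function(p) {
        caller_profile(base_fp_het_rate = 0, dup_fp_multiplier = 1,
                       het_undercall = FALSE, min_depth = 4)
      }),
      chip_error_rate = 0, coverage_mean = 60, seed = seed
    ),
    paperlike = sim_config(seed = seed),
    adversarial = sim_config(
      caller_profiles = list(
        noisy1 = caller_profile(base_fp_het_rate = 3e-4, dup_fp_multiplier = 10,
                                het_undercall = TRUE, fp_vaf_shape = c(1, 6),
                                tp_vaf_shape = c(10, 10)),
        noisy2 = caller_profile(base_fp_het_rate = 3e-4, dup_fp_multiplier = 10,
                                het_undercall = TRUE, fp_vaf_shape = c(1, 6),
                                tp_vaf_shape = c(10, 10))
      ),
      seed = seed
    )
  )
  sim <- simulate_genome(config)
  if (!is.null(dir)) write_sim_bundle(sim, dir)
  sim
}
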