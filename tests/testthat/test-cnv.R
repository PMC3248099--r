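make_grid <- function(n, chrom = "chr1", window = 1000) {
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * window,
                 end = seq_len(n) * window)
}

test_that("read-depth caller finds planted runs and respects the run-length rule", {
  g <- make_grid(40)
  g$count_test <- 100
  g$count_ref <- 100
  expect_equal(nrow(call_cnv_readdepth(g)), 0) # equal counts everywhere

  # planted 5-window region with test counts 4x ref (Poisson noise)
  withr::local_seed(131)
  g2 <- make_grid(40)
  g2$count_ref <- rpois(40, 100)
  mu <- rep(100, 40)
  mu[16:20] <- 400
  g2$count_test <- rpois(40, mu)
  calls <- call_cnv_readdepth(g2)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$cnv_type, "duplication")
  expect_lte(abs(calls$start - 15000), 1000)
  expect_lte(abs(calls$end - 20000), 1000)

  # sub-threshold 4-window run is not called
  g3 <- make_grid(40)
  g3$count_ref <- rpois(40, 100)
  mu3 <- rep(100, 40)
  mu3[16:19] <- 400
  g3$count_test <- rpois(40, mu3)
  expect_equal(nrow(call_cnv_readdepth(g3)), 0)

  expect_error(call_cnv_readdepth(dplyr::mutate(g, count_ref = 0)), "all zero")
})

test_that("swapping test and reference negates log2 and swaps call labels", {
  withr::local_seed(141)
  g <- make_grid(60)
  mu <- rep(100, 60)
  mu[11:20] <- 420
  mu[41:48] <- 12
  g$count_test <- rpois(60, mu)
  g$count_ref <- rpois(60, 100)
  fwd <- call_cnv_readdepth(g)
  swapped <- dplyr::rename(g, count_test = count_ref, count_ref = count_test)
  rev <- call_cnv_readdepth(swapped)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$mean_log2, -rev$mean_log2)
  expect_equal(fwd$cnv_type,
               ifelse(rev$cnv_type == "duplication", "deletion", "duplication"))
})

test_that("estimated copy number recovers planted CN within 15% at high coverage", {
  withr::local_seed(151)
  # the CNV must be a small fraction of the genome or total-count
  # normalization itself shifts the ratio
  for (cn in c(1, 3, 4)) {
    g <- make_grid(300)
    g$count_ref <- rpois(300, 500)
    mu <- rep(500, 300)
    mu[141:160] <- 500 * cn / 2
    g$count_test <- rpois(300, mu)
    calls <- call_cnv_readdepth(g, rd_params(min_abs_log2 = 0.3))
    hit <- calls[calls$start < 160000 & calls$end > 140000, ]
    expect_gte(nrow(hit), 1)
    est <- estimate_copy_number(sum(hit$mean_log2 * hit$n_windows) /
                                  sum(hit$n_windows))
    expect_lt(abs(est - cn) / cn, 0.15, label = paste("CN", cn, "est", est))
  }
})

test_that("cross-platform overlap uses the 1 bp half-open rule and matches brute force", {
  cnvs <- tibble::tibble(
    chrom = "chr1",
    start = c(0, 99, 100, 300),
    end = c(100, 200, 200, 400),
    cnv_type = "duplication",
    platform = c("readdepth", "cgh", "snp_array", "cgh")
  )
  res <- cnv_overlap_compare(cnvs)
  # [0,100) overlaps [99,200) by 1 bp; [0,100) vs [100,200) does not
  expect_equal(res$cnvs$shared, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(nrow(res$consensus), 1)
  expect_equal(res$consensus$start, 0)
  expect_equal(res$consensus$end, 200)

  # random 3-platform sets vs an all-pairs brute-force shared flag
  withr::local_seed(161)
  rand <- purrr::map(c("readdepth", "cgh", "snp_array"), function(pf) {
    start <- sample.int(2e6, 30)
    tibble::tibble(chrom = "chr1", start = start,
                   end = start + sample(500:5000, 30, replace = TRUE),
                   cnv_type = sample(c("duplication", "deletion"), 30, TRUE),
                   platform = pf)
  }) |> purrr::list_rbind()
  got <- cnv_overlap_compare(rand)
  brute_shared <- vapply(seq_len(nrow(rand)), function(i) {
    any(rand$platform != rand$platform[i] &
          rand$start < rand$end[i] & rand$end > rand$start[i])
  }, logical(1))
  expect_equal(got$cnvs$shared, brute_shared)
  # every consensus region contains >= 2 platforms
  expect_true(all(got$consensus$n_platforms >= 2))
})

test_that("CNV summaries equal independent recomputation", {
  withr::local_seed(171)
  start <- sample.int(1e6, 50)
  cnvs <- tibble::tibble(chrom = "chr1", start = start,
                         end = start + sample(1000:9000, 50, replace = TRUE))
  s <- cnv_summary(cnvs, genome_layout("chr1", 2e6))
  len <- sort(cnvs$end - cnvs$start)
  expect_equal(s$n, 50)
  expect_equal(s$total_bp, sum(len))
  expect_equal(s$mean_length, mean(len))
  expect_equal(s$min_length, len[1])
  expect_equal(s$max_length, len[50])
  expect_equal(s$genome_fraction, sum(len) / 2e6)

  expect_warning(s0 <- cnv_summary(cnvs[0, ]), "empty")
  expect_equal(s0$n, 0)

  expect_equal(cnv_summary(tibble::tibble(chrom = "c", start = 0, end = 1000))$mean_length, 1000)
})

test_that("cross-assembly filter keeps same-chromosome SVs and reports reductions", {
  svs <- tibble::tibble(
    sv_id = paste0("sv", 1:4),
    class = c("inversion", "inversion", "translocation", "inversion"),
    chrom1 = "chrA5", pos1 = c(100, 200, 300, 400),
    chrom2 = "chrA5", pos2 = c(150, 250, 350, 450)
  )
  pm <- tibble::tibble(
    chrom_a = "chrA5",
    pos_a = c(100, 150, 200, 250, 300, 350, 400),
    chrom_b = c("chrB5", "chrB5", "chrB5", "chrB7", "chrB2", "chrB2", "chrB1")
    # sv1 both -> chrB5 (kept); sv2 -> chrB5/chrB7 (removed);
    # sv3 both -> chrB2 (kept); sv4 has an unmapped breakpoint (450)
  )
  pm$pos_b <- pm$pos_a + 10
  res <- cross_assembly_filter(svs, pm)
  expect_equal(res$kept$sv_id, c("sv1", "sv3"))
  rep_inv <- res$report[res$report$class == "inversion", ]
  expect_equal(rep_inv$before, 3)
  expect_equal(rep_inv$after, 1)
  expect_equal(rep_inv$n_unmapped, 1)
  expect_equal(res$overall_reduction_pct, 50)
})

test_that("permutation gene enrichment is calibrated, reproducible and matches closed form", {
  layout <- genome_layout(c("chr1", "chr2"), c(6e6, 4e6))
  withr::local_seed(181)
  # dense gene set so the null count is large relative to its spread
  genes <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 2000, TRUE, prob = c(0.6, 0.4))
  )
  genes$start <- vapply(genes$chrom, function(ch) {
    sample.int(ifelse(ch == "chr1", 6e6, 4e6) - 5000, 1) - 1
  }, numeric(1))
  genes$end <- genes$start + 5000

  # genes covering the genome completely -> any placement hits exactly one
  # gene, so fold is exactly 1
  covering <- tibble::tibble(chrom = layout$chrom, start = 0,
                             end = layout$length)
  cnv1 <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1.2e6)
  full <- gene_enrichment_permutation(cnv1, covering, layout, n_perm = 100, seed = 1)
  expect_equal(full$fold, 1)
  expect_true(all(full$null == 1))

  # fixed seed -> bit-identical
  cnvs <- tibble::tibble(chrom = rep(c("chr1", "chr2"), c(90, 60)),
                         start = c(sample.int(6e6 - 3e4, 90),
                                   sample.int(4e6 - 3e4, 60)) - 1)
  cnvs$end <- cnvs$start + 3e4
  r1 <- gene_enrichment_permutation(cnvs, genes, layout, n_perm = 200, seed = 9)
  r2 <- gene_enrichment_permutation(cnvs, genes, layout, n_perm = 200, seed = 9)
  expect_identical(r1$null, r2$null)

  # uniformly placed CNVs -> fold near 1
  r3 <- gene_enrichment_permutation(cnvs, genes, layout, n_perm = 1000, seed = 10)
  expect_lt(abs(r3$fold - 1), 0.1)

  # single-interval null mean matches exhaustive placement enumeration
  lay1 <- genome_layout("chr1", 20000)
  genes1 <- tibble::tibble(chrom = "chr1", start = c(1000, 5000, 12000),
                           end = c(1400, 5600, 12800))
  cnv_one <- tibble::tibble(chrom = "chr1", start = 0, end = 900)
  w <- 900
  exact <- mean(vapply(0:(20000 - w), function(s) {
    sum(s < genes1$end & (s + w) > genes1$start)
  }, numeric(1)))
  r4 <- gene_enrichment_permutation(cnv_one, genes1, lay1, n_perm = 4000, seed = 2)
  expect_lt(abs(r4$null_mean - exact), 0.05)

  expect_error(
    gene_enrichment_permutation(tibble::tibble(chrom = "chr1", start = 0, end = 3e7),
                                genes, layout, seed = 1),
    "longer than every chromosome"
  )
})

test_that("validation bookkeeping excludes assay failures from the denominator", {
  expect_equal(validation_rate(rep("confirmed", 5))$confirmation_rate, 1)
  withr::local_seed(191)
  labels <- sample(c("confirmed", "not_confirmed", "assay_failed"), 60,
                   replace = TRUE, prob = c(0.6, 0.2, 0.2))
  r <- validation_rate(labels)
  expect_equal(r$confirmation_rate,
               sum(labels == "confirmed") / sum(labels != "assay_failed"))
  expect_warning(rf <- validation_rate(rep("assay_failed", 3)), "undefined")
  expect_true(is.na(rf$confirmation_rate))
  expect_error(validation_rate("maybe"), "unknown outcome")
})
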