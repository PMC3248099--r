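test_that("caller intersection keeps identically represented indels", {
  a <- make_calls("chr1", c(10, 20, 30), ref = "AT", alt = "A", caller = "dindel")
  b <- make_calls("chr1", c(10, 30, 40), ref = "AT", alt = "A", caller = "mpileup")
  expect_equal(intersect_indel_callers(a, a)$pos, a$pos)
  expect_equal(intersect_indel_callers(a, b)$pos, c(10, 30))
  expect_equal(nrow(intersect_indel_callers(a, b[b$pos == 40, ])), 0)

  # independent drop-out: |A ∩ B| ~ Binomial(n, 0.9 * 0.85)
  withr::local_seed(81)
  n <- 1000
  truth <- make_calls("chr1", seq_len(n) * 50, ref = "AT", alt = "A")
  keep_a <- runif(n) > 0.10
  keep_b <- runif(n) > 0.15
  got <- nrow(intersect_indel_callers(truth[keep_a, ], truth[keep_b, ]))
  ci <- qbinom(c(0.025, 0.975), n, 0.9 * 0.85)
  expect_gte(got, ci[1])
  expect_lte(got, ci[2])
})

test_that("six-criterion indel filter matches manual evaluation and is idempotent", {
  n_mask <- tibble::tibble(chrom = "chr1", start = 500, end = 600)
  indels <- make_calls("chr1", c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100, 550, 110),
                       ref = "AT", alt = "A")
  indels$fwd_support <- c(1, 0, 1, 1, 1, 1, 2, 3, 1, 1, 1, NA)
  indels$rev_support <- c(1, 2, 0, 1, 1, 1, 2, 3, 1, 1, 1, 1)
  indels$base_quality <- c(30, 30, 30, 19, 30, 30, 20, 30, 30, 30, 30, 30)
  indels$depth <- c(10, 10, 10, 10, 3, 31, 4, 30, 10, 10, 10, 10)
  # manual application of all rules:
  #  pos 10 ok; 20 no fwd; 30 no rev; 40 low bq; 50 depth<4; 60 depth>30;
  #  70 ok (boundaries inclusive); 80 ok; 90 ok; 100 ok; 550 in N mask;
  #  110 missing annotation
  out <- filter_indels(indels, n_mask = n_mask)
  expect_equal(out$pos, c(10, 70, 80, 90, 100))
  expect_equal(attr(out, "n_missing_annotation"), 1)
  expect_equal(attr(out, "n_removed"), 7)

  # idempotent
  again <- filter_indels(out, n_mask = n_mask)
  expect_equal(again$pos, out$pos)

  # survivors equal the intersection of each criterion applied alone
  p <- indel_filter_params()
  solo <- list(
    filter_indels(indels, indel_filter_params(min_base_quality = 0, min_depth = 0,
                                              max_depth = Inf, exclude_n_overlap = FALSE)),
    filter_indels(indels, indel_filter_params(min_depth = 0, max_depth = Inf,
                                              require_both_strands = FALSE,
                                              exclude_n_overlap = FALSE)),
    filter_indels(indels, indel_filter_params(min_base_quality = 0,
                                              require_both_strands = FALSE,
                                              exclude_n_overlap = FALSE)),
    filter_indels(indels, indel_filter_params(min_base_quality = 0, min_depth = 0,
                                              max_depth = Inf,
                                              require_both_strands = FALSE),
                  n_mask = n_mask)
  )
  inter <- Reduce(intersect, lapply(solo, function(x) x$pos))
  expect_equal(sort(out$pos), sort(inter))
})

test_that("3n classification and chi-square match a textbook hand computation", {
  res <- classify_3n(c(3, 6, 9), c(1, 2, 4))
  expect_equal(unname(res$table["coding", "3n"]), 3)
  expect_equal(res$frac_3n_coding, 1)
  expect_equal(unname(res$table["background", "non_3n"]), 3)

  withr::local_seed(91)
  coding <- ifelse(runif(400) < 0.5, 3, 1 + (runif(400) > 0.5))
  background <- ifelse(runif(400) < 0.11, 3, 1 + (runif(400) > 0.5))
  res2 <- classify_3n(coding, background)
  # hand chi-square on the 2x2 table
  tab <- res2$table
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  hand <- sum((tab - expected)^2 / expected)
  expect_equal(res2$statistic, hand)
  expect_equal(res2$p_value, pchisq(hand, df = 1, lower.tail = FALSE))
  expect_lt(res2$p_value, 1e-6)

  expect_error(classify_3n(numeric(0), c(3)), "non-empty")
})

test_that("relative protein position walks the CDS strand-aware", {
  # plus strand, single 303 bp CDS (100 aa + stop)
  gene <- tibble::tibble(chrom = "chr1", start = 1000, end = 1303, strand = "+")
  expect_equal(relative_protein_position(1000, gene), 0.01) # first codon
  expect_equal(relative_protein_position(1299, gene), 1.0)  # last codon (pos in codon 100)
  expect_error(relative_protein_position(999, gene), "outside the CDS")

  # minus strand, two CDS exons: oracle walks CDS bases explicitly 3' -> 5'
  gene_m <- tibble::tibble(chrom = "chr1", start = c(100, 400), end = c(250, 556),
                           strand = "-")
  oracle <- function(pos) {
    # genomic CDS coordinates in translation order (descending for minus)
    coords <- rev(c(100:249, 400:555))
    off <- which(coords == pos) - 1
    protein_length <- length(coords) / 3 - 1
    min(floor(off / 3) + 1, protein_length) / protein_length
  }
  for (pos in c(555, 500, 420, 400, 249, 150, 100)) {
    expect_equal(relative_protein_position(pos, gene_m), oracle(pos),
                 info = paste("pos", pos))
  }

  # uniform placement gives a uniform position distribution
  withr::local_seed(101)
  gene_u <- tibble::tibble(chrom = "chr1", start = 0, end = 3003, strand = "+")
  rel <- vapply(sample(0:3002, 400, replace = TRUE),
                function(p) relative_protein_position(p, gene_u), numeric(1))
  expect_true(all(rel > 0 & rel <= 1))
  ks <- suppressWarnings(ks.test(rel, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("snp:indel ratios divide printed-style counts correctly", {
  expect_equal(snp_indel_ratio(100, 100), 1)
  expect_equal(round(snp_indel_ratio(2859650, 197895), 2), 14.45)
  expect_error(snp_indel_ratio(10, 0), "> 0")
})

test_that("region density enrichment recovers planted fold changes", {
  layout <- genome_layout("chr1", 1e7)
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 5e6)

  withr::local_seed(111)
  # null: uniform variants, half the genome -> fold ~ 1
  v <- make_calls("chr1", sample.int(1e7, 5000) - 1)
  e0 <- region_density_enrichment(v, regions, layout)
  expect_gt(e0$fold, 0.9)
  expect_lt(e0$fold, 1.1)
  expect_gt(e0$p_value, 0.001)

  # planted 3.3-fold excess inside regions
  n_in <- round(5000 * 3.3 / 4.3)
  v2 <- make_calls("chr1", c(sample.int(5e6, n_in),
                             5e6 + sample.int(5e6, 5000 - n_in)) - 1)
  e2 <- region_density_enrichment(v2, regions, layout)
  expect_lt(abs(e2$fold - 3.3) / 3.3, 0.1)
  expect_lt(e2$p_value, 1e-6)

  # X-versus-autosome mode: X density planted 4.9x lower
  layx <- genome_layout(c("chr1", "chrX"), c(8e6, 4e6), sex_chroms = "chrX")
  n_x <- round(3000 * (4e6 / 4.9) / (8e6 + 4e6 / 4.9))
  vx <- dplyr::bind_rows(
    make_calls("chrX", sample.int(4e6, n_x) - 1),
    make_calls("chr1", sample.int(8e6, 3000 - n_x) - 1)
  )
  ex <- region_density_enrichment(
    vx, tibble::tibble(chrom = "chrX", start = 0, end = 4e6), layx
  )
  expect_lt(abs(1 / ex$fold - 4.9) / 4.9, 0.15)

  expect_error(
    region_density_enrichment(v, regions[0, ], layout),
    "0 bases"
  )
})

test_that("windowed SNP-indel density correlation behaves across regimes", {
  layout <- genome_layout("chr1", 6e6) # 300 windows of 20 kb
  withr::local_seed(121)
  snps <- make_calls("chr1", sample.int(6e6, 6000) - 1)

  # indels identical to snps -> r = 1
  r1 <- windowed_density_correlation(snps, snps, layout)
  expect_equal(r1$r, 1)

  # independent placement -> R^2 near 0 (5,000 windows)
  lay_big <- genome_layout("chr1", 1e8)
  s_b <- make_calls("chr1", sample.int(1e8, 20000) - 1)
  i_b <- make_calls("chr1", sample.int(1e8, 20000) - 1, ref = "AT", alt = "A")
  r0 <- windowed_density_correlation(s_b, i_b, lay_big)
  expect_equal(r0$n_windows, 5000)
  expect_lt(abs(r0$r), 0.1)

  # shared latent rate calibrated to R^2 = 0.4:
  # counts X,Y ~ Poisson(lam), lam ~ Gamma with var v solving v/(m+v) = sqrt(0.4)
  m <- 20
  v <- sqrt(0.4) / (1 - sqrt(0.4)) * m
  lam <- rgamma(300, shape = m^2 / v, scale = v / m)
  place <- function(counts, ref = "A", alt = "G") {
    pos <- unlist(purrr::map(seq_along(counts), function(i) {
      if (counts[i] == 0) return(NULL)
      (i - 1) * 2e4 + seq_len(counts[i])
    }))
    make_calls("chr1", pos, ref = ref, alt = alt)
  }
  rc <- windowed_density_correlation(place(rpois(300, lam)),
                                     place(rpois(300, lam), "AT", "A"),
                                     layout)
  expect_gt(rc$r_squared, 0.3)
  expect_lt(rc$r_squared, 0.5)

  # zero variance flagged
  flat <- place(rep(1, 300))
  expect_warning(rz <- windowed_density_correlation(flat, flat, layout),
                 "zero variance")
  expect_true(is.na(rz$r))
})
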