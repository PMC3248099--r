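# shared builders for small in-code fixtures

make_calls <- function(chrom, pos, ref = "A", alt = "G",
                       zygosity = "het", depth = 20,
                       ad_ref = 12, ad_alt = 8, caller = "bwa") {
  tibble::tibble(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    vtype = ifelse(
      nchar(ref) == 1 & nchar(alt) == 1, "snp",
      ifelse(nchar(alt) > nchar(ref), "insertion", "deletion")
    ),
    zygosity = zygosity, depth = depth, ad_ref = ad_ref, ad_alt = ad_alt,
    caller = caller
  )
}

toy_layout <- function() {
  genome_layout(c("chr1", "chr2"), c(5e6, 3e6))
}

# gene dropping: simulate founder-allele transmission, F = P(the two alleles
# of the individual are copies of the same founder allele)
gene_drop_f <- function(ped, individual, n_drops) {
  ped <- varconcord:::pedigree_order(ped)
  alleles <- list()
  next_id <- 1L
  for (i in seq_len(nrow(ped))) {
    id <- ped$id[i]
    pick <- function(parent) {
      if (is.na(parent)) {
        a <- rep(next_id, n_drops)
        next_id <<- next_id + 1L
        a
      } else {
        pa <- alleles[[parent]]
        sel <- runif(n_drops) < 0.5
        ifelse(sel, pa[[1]], pa[[2]])
      }
    }
    alleles[[id]] <- list(pick(ped$sire[i]), pick(ped$dam[i]))
  }
  mean(alleles[[individual]][[1]] == alleles[[individual]][[2]])
}

# apply an anchored variant to a sequence string (oracle for normalization)
apply_variant <- function(seq, pos, ref, alt) {
  stopifnot(substr(seq, pos + 1, pos + nchar(ref)) == ref)
  paste0(substr(seq, 1, pos), alt, substr(seq, pos + 1 + nchar(ref), nchar(seq)))
}
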