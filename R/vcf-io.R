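#' Read a single-sample VCF into a tidy call table
#'
#' Supports the VCF 4.2 subset used throughout this package: `CHROM POS ID
#' REF ALT QUAL FILTER INFO FORMAT sample` with `GT`, `DP` and `AD` FORMAT
#' fields. The 1-based VCF positions are converted to the internal 0-based
#' convention at this boundary; multi-allelic records are split into one row
#' per alternate allele carried by the genotype.
#'
#' Records with an unparseable genotype (e.g. `./.` or allele indices beyond
#' the ALT list) are skipped; a single warning reports how many.
#'
#' @param path Path to a VCF file (plain text).
#' @param caller Caller identifier stored in the `caller` column. Defaults
#'   to the VCF sample name.
#' @return A tibble of variant calls with columns `chrom`, `pos` (0-based),
#'   `ref`, `alt`, `vtype` (`snp`/`insertion`/`deletion`), `zygosity`
#'   (`hom_ref`/`het`/`hom_alt`), `depth`, `ad_ref`, `ad_alt`, `caller`.
#' @seealso [write_vcf()], [normalize_indels()]
#' @export
read_vcf <- function(path, caller = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_mat <- v@gt
  if (ncol(gt_mat) < 2) abort("VCF has no sample column")
  sample_name <- colnames(gt_mat)[2]
  caller <- caller %||% sample_name

  pos1 <- suppressWarnings(as.numeric(fix[, "POS"]))
  bad <- which(is.na(pos1) | is.na(fix[, "REF"]) | fix[, "REF"] == "")
  if (length(bad) > 0) {
    abort(sprintf("malformed VCF record at data line %d of %s", bad[1], path))
  }

  n_skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(gt_mat[i, 1], ":", fixed = TRUE)[[1]]
    val <- strsplit(gt_mat[i, 2], ":", fixed = TRUE)[[1]]
    gt <- val[match("GT", fmt)]
    dp <- suppressWarnings(as.numeric(val[match("DP", fmt)]))
    ad <- val[match("AD", fmt)]
    ad <- if (is.na(ad)) NA_real_ else suppressWarnings(as.numeric(strsplit(ad, ",", fixed = TRUE)[[1]]))
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]

    al <- strsplit(gsub("|", "/", gt %||% ".", fixed = TRUE), "/", fixed = TRUE)[[1]]
    al_num <- suppressWarnings(as.integer(al))
    if (length(al_num) != 2 || anyNA(al_num) || any(al_num > length(alts))) {
      n_skipped <- n_skipped + 1L
      next
    }
    ref <- fix[i, "REF"]
    alt_idx <- sort(unique(al_num[al_num > 0]))
    if (length(alt_idx) == 0) {
      # homozygous reference genotype
      rows[[i]] <- tibble(
        chrom = fix[i, "CHROM"], pos = pos1[i] - 1, ref = ref,
        alt = if (length(alts) >= 1 && !is.na(alts[1]) && alts[1] != ".") alts[1] else NA_character_,
        zygosity = "hom_ref", depth = dp,
        ad_ref = if (length(ad) >= 1) ad[1] else NA_real_, ad_alt = NA_real_
      )
      next
    }
    rows[[i]] <- purrr::map(alt_idx, function(a) {
      tibble(
        chrom = fix[i, "CHROM"], pos = pos1[i] - 1, ref = ref, alt = alts[a],
        zygosity = if (al_num[1] == al_num[2]) "hom_alt" else "het",
        depth = dp,
        ad_ref = if (length(ad) >= 1) ad[1] else NA_real_,
        ad_alt = if (length(ad) >= a + 1) ad[a + 1] else NA_real_
      )
    }) |> purrr::list_rbind()
  }
  if (n_skipped > 0) {
    warn(sprintf("skipped %d record(s) with unparseable genotypes", n_skipped))
  }
  out <- purrr::list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), pos = numeric(), ref = character(),
                  alt = character(), zygosity = character(), depth = numeric(),
                  ad_ref = numeric(), ad_alt = numeric())
  }
  out |>
    mutate(vtype = variant_type(.data$ref, .data$alt), caller = caller) |>
    select("chrom", "pos", "ref", "alt", "vtype", "zygosity",
           "depth", "ad_ref", "ad_alt", "caller")
}

variant_type <- function(ref, alt) {
  dplyr::case_when(
    is.na(alt) ~ NA_character_,
    nchar(ref) == 1 & nchar(alt) == 1 ~ "snp",
    nchar(alt) > nchar(ref) ~ "insertion",
    TRUE ~ "deletion"
  )
}

#' Write a tidy call table as a single-sample VCF
#'
#' Inverse of [read_vcf()] on the supported subset: positions are converted
#' back to 1-based and genotypes encoded as `GT:DP:AD`. Output is
#' deterministic for a given input (rows are written in input order).
#'
#' @param calls Call tibble (one caller) as produced by [read_vcf()] or the
#'   simulator.
#' @param path Output path.
#' @param sample Sample column name; defaults to the caller id.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample = NULL) {
  sample <- sample %||% (if ("caller" %in% names(calls)) calls$caller[1] else "sample")
  gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[calls$zygosity]
  ad <- ifelse(
    is.na(calls$ad_ref) & is.na(calls$ad_alt), ".",
    paste0(ifelse(is.na(calls$ad_ref), 0, calls$ad_ref), ",",
           ifelse(is.na(calls$ad_alt), 0, calls$ad_alt))
  )
  dp <- ifelse(is.na(calls$depth), ".", format(calls$depth, scientific = FALSE, trim = TRUE))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  body <- sprintf(
    "%s\t%s\t.\t%s\t%s\t.\tPASS\t.\tGT:DP:AD\t%s:%s:%s",
    calls$chrom, format(calls$pos + 1, scientific = FALSE, trim = TRUE),
    calls$ref, ifelse(is.na(calls$alt), ".", calls$alt), gt, dp, ad
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Left-normalize indel representations
#'
#' Shifts each insertion/deletion as far left as the reference sequence
#' allows (the standard left-alignment used before intersecting call sets
#' from different callers, whose representations of the same indel in a
#' repeat can differ). Also trims redundant shared leading/trailing bases.
#' SNPs pass through unchanged.
#'
#' @param calls Call tibble (see [read_vcf()]).
#' @param ref_seqs Named character vector: chromosome name -> reference
#'   sequence (A/C/G/T string). Chromosomes absent from `ref_seqs` are left
#'   unmodified with a warning.
#' @return The call tibble with normalized `pos`, `ref`, `alt`, `vtype`.
#' @export
normalize_indels <- function(calls, ref_seqs) {
  missing_chr <- setdiff(unique(calls$chrom[calls$vtype != "snp"]), names(ref_seqs))
  if (length(missing_chr) > 0) {
    warn(paste0("no reference sequence for: ", paste(missing_chr, collapse = ", "),
                "; records left unnormalized"))
  }
  idx <- which(calls$vtype %in% c("insertion", "deletion") &
                 calls$chrom %in% names(ref_seqs))
  for (i in idx) {
    nv <- normalize_one(calls$pos[i], calls$ref[i], calls$alt[i],
                        ref_seqs[[calls$chrom[i]]])
    calls$pos[i] <- nv$pos
    calls$ref[i] <- nv$ref
    calls$alt[i] <- nv$alt
  }
  calls$vtype <- variant_type(calls$ref, calls$alt)
  calls
}

# one anchored indel; seq is the chromosome string, pos 0-based
normalize_one <- function(pos, ref, alt, seq) {
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim shared trailing bases
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # trim shared leading bases, keeping one anchor
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  ref <- paste(r, collapse = "")
  alt <- paste(a, collapse = "")
  if (nchar(ref) == nchar(alt)) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  base_at <- function(p) substr(seq, p + 1, p + 1) # 0-based lookup
  if (nchar(ref) > nchar(alt)) {
    # deletion of segment [pos+1, pos+1+k)
    k <- nchar(ref) - 1
    d <- pos + 1
    # shifting to d-1 needs a new anchor base at d-2
    while (d >= 2 && base_at(d - 1) == base_at(d + k - 1)) d <- d - 1
    pos <- d - 1
    ref <- substr(seq, pos + 1, pos + 1 + k)
    alt <- base_at(pos)
  } else {
    # insertion of s before position d = pos+1
    s <- strsplit(substr(alt, 2, nchar(alt)), "")[[1]]
    k <- length(s)
    d <- pos + 1
    while (d >= 2 && base_at(d - 1) == s[k]) {
      s <- c(s[k], s[-k])
      d <- d - 1
    }
    pos <- d - 1
    ref <- base_at(pos)
    alt <- paste0(ref, paste(s, collapse = ""))
  }
  list(pos = pos, ref = ref, alt = alt)
}
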