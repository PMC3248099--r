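#' Read a pedigree table
#'
#' TSV with columns `id`, `sire`, `dam`; `"0"`, `""` or missing denote an
#' unknown parent. Unknown parents are treated as unique unrelated
#' founders.
#'
#' @param path File path.
#' @return Tibble `id`, `sire`, `dam` (unknown as `NA`).
#' @export
read_pedigree <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  clean <- function(x) ifelse(is.na(x) | x %in% c("0", ""), NA_character_, x)
  tibble(id = df$id, sire = clean(df$sire), dam = clean(df$dam))
}

# order individuals so parents precede offspring; error on cycles
pedigree_order <- function(ped) {
  # add parents that appear only as sire/dam, as founders
  extra <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(extra) > 0) {
    ped <- bind_rows(ped, tibble(id = extra, sire = NA_character_,
                                 dam = NA_character_))
  }
  if (anyDuplicated(ped$id)) abort("duplicate individual ids in pedigree")
  ids <- ped$id
  placed <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% placed) &
      (is.na(remaining$dam) | remaining$dam %in% placed)
    if (!any(ready)) abort("pedigree contains a cycle")
    placed <- c(placed, remaining$id[ready])
    remaining <- remaining[!ready, ]
  }
  ped[match(placed, ped$id), ]
}

#' Additive (numerator) relationship matrix by the tabular method
#'
#' Builds Wright's numerator relationship matrix A recursively in pedigree
#' order: for individual i with parents s and d, `a_ii = 1 + a_sd/2` and
#' `a_ij = (a_sj + a_dj)/2` for previously placed j; unknown parents
#' contribute 0. The kinship matrix is A/2 and `F_i = a_ii - 1`.
#'
#' @param ped Pedigree tibble (`id`, `sire`, `dam`; `NA` = unknown).
#' @return The A matrix with individual ids as dimnames.
#' @export
relationship_matrix <- function(ped) {
  ped <- pedigree_order(ped)
  n <- nrow(ped)
  a <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  idx <- setNames(seq_len(n), ped$id)
  for (i in seq_len(n)) {
    s <- ped$sire[i]
    d <- ped$dam[i]
    si <- if (is.na(s)) NA_integer_ else idx[[s]]
    di <- if (is.na(d)) NA_integer_ else idx[[d]]
    a_sd <- if (!is.na(si) && !is.na(di)) a[si, di] else 0
    a[i, i] <- 1 + a_sd / 2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        a_sj <- if (!is.na(si)) a[si, j] else 0
        a_dj <- if (!is.na(di)) a[di, j] else 0
        a[i, j] <- a[j, i] <- (a_sj + a_dj) / 2
      }
    }
  }
  a
}

#' Kinship matrix of a pedigree
#'
#' @inheritParams relationship_matrix
#' @return Symmetric matrix of kinship coefficients (A/2).
#' @export
kinship_matrix <- function(ped) relationship_matrix(ped) / 2

#' Wright's inbreeding coefficient of an individual
#'
#' F equals the kinship between the parents: `F_i = a_sd / 2` from the
#' tabular relationship matrix. Founders (and any individual with an
#' unknown parent) have F = 0.
#'
#' @param ped Pedigree tibble (`id`, `sire`, `dam`).
#' @param individual Id of the individual.
#' @return F in [0, 1).
#' @examples
#' ped <- tibble::tibble(
#'   id = c("gs", "gd", "s", "d", "x"),
#'   sire = c(NA, NA, "gs", "gs", "s"),
#'   dam = c(NA, NA, "gd", "gd", "d")
#' )
#' inbreeding_coefficient(ped, "x") # full-sib mating: 0.25
#' @export
inbreeding_coefficient <- function(ped, individual) {
  if (!individual %in% ped$id) abort("individual not in pedigree")
  a <- relationship_matrix(ped)
  unname(a[individual, individual] - 1)
}
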