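#' Pedigree kinship matrix
#'
#' Kinship (coancestry) coefficients from a topologically ordered pedigree
#' by the tabular method: for animal `i` later in the pedigree than `j`,
#' `f(i, j) = (f(sire_i, j) + f(dam_i, j)) / 2` with unknown parents
#' contributing 0, and `f(i, i) = (1 + f(sire_i, dam_i)) / 2`. Founders are
#' assumed unrelated and non-inbred, so founder-founder off-diagonals are 0
#' and non-inbred diagonals are exactly 0.5.
#'
#' @param pedigree a pedigree data.frame (see [simulate_pedigree()]).
#' @return Symmetric numeric matrix with animal-id dimnames; entries in
#'   `[0, 1]`.
#' @export
pedigree_kinship <- function(pedigree) {
  validate_pedigree(pedigree)
  n <- nrow(pedigree)
  ids <- pedigree$animal_id
  si <- match(pedigree$sire_id, ids)
  di <- match(pedigree$dam_id, ids)
  f <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * f[s, j]
      if (!is.na(d)) row <- row + 0.5 * f[d, j]
      f[i, j] <- row
      f[j, i] <- row
    }
    fsd <- if (!is.na(s) && !is.na(d)) f[s, d] else 0
    f[i, i] <- 0.5 * (1 + fsd)
  }
  f
}
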