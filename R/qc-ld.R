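#' Permutation test for genotypic linkage disequilibrium
#'
#' Log-likelihood-ratio G statistic on the 3x3 genotype contingency table
#' of two loci over the individuals non-missing at both, with significance
#' from a Monte-Carlo permutation null obtained by shuffling one locus's
#' genotypes across individuals:
#' p = (1 + #\{permuted G >= observed G\}) / (n_permutations + 1).
#'
#' @param locus_i,locus_j Integer score vectors (0/1/2/NA) of equal length.
#' @param n_permutations Number of permutations.
#' @param seed Optional seed.
#' @return A list with `g`, `p_value`, `n` (shared individuals) and
#'   `skipped` (TRUE when either locus has fewer than two distinct
#'   genotypes among the shared individuals; `p_value` is then `NA`).
#' @export
genotypic_ld_test <- function(locus_i, locus_j, n_permutations = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ok <- !is.na(locus_i) & !is.na(locus_j)
  x <- locus_i[ok]; y <- locus_j[ok]
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(g = NA_real_, p_value = NA_real_, n = sum(ok), skipped = TRUE))
  }
  g_obs <- g_stat(x, y)
  ge <- vapply(seq_len(n_permutations),
               function(i) g_stat(x, sample(y)), numeric(1))
  p <- (1 + sum(ge >= g_obs - 1e-12)) / (n_permutations + 1)
  list(g = g_obs, p_value = p, n = sum(ok), skipped = FALSE)
}

g_stat <- function(x, y) {
  o <- matrix(tabulate(3L * x + y + 1L, 9L), 3, 3, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  keep <- o > 0
  2 * sum(o[keep] * log(o[keep] / e[keep]))
}
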