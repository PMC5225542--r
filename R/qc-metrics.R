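#' Per-locus quality metrics
#'
#' Computes, for every locus, the call rate (non-missing / total), minor
#' allele frequency, polymorphic information content
#' PIC = 1 - (p^2 + q^2) - 2 p^2 q^2, observed heterozygote fraction, a
#' monomorphic flag (MAF = 0), and -- when replicate pairs are supplied --
#' the repeatability, i.e. the fraction of concordant non-missing calls
#' across replicate pairs. A locus with every call missing gets call rate
#' 0, MAF 0 and the monomorphic flag.
#'
#' @param G A [geno_matrix()].
#' @param replicate_pairs Optional tibble with columns `id`, `replicate`
#'   naming replicate individual pairs present in `G`. When absent,
#'   repeatability falls back to the value stored in the locus metadata
#'   (as delivered on a DArT report), or `NA`.
#' @return A tibble with one row per locus: `locus`, `clone_id`,
#'   `call_rate`, `maf`, `pic`, `obs_het`, `repeatability`, `monomorphic`.
#' @export
locus_metrics <- function(G, replicate_pairs = NULL) {
  stopifnot(inherits(G, "geno_matrix"), ncol(G$scores) > 0)
  s <- G$scores
  d <- geno_dosage(G)
  called <- !is.na(s)
  n_called <- colSums(called)
  call_rate <- n_called / nrow(s)
  alt <- colSums(d, na.rm = TRUE)
  p <- ifelse(n_called > 0, alt / (2 * n_called), 0)
  maf <- pmin(p, 1 - p)
  q <- 1 - p
  pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
  obs_het <- ifelse(n_called > 0, colSums(s == 2L, na.rm = TRUE) / n_called, 0)

  repeatability <- G$loci$repeatability
  if (!is.null(replicate_pairs) && nrow(replicate_pairs) > 0) {
    a <- s[replicate_pairs$id, , drop = FALSE]
    b <- s[replicate_pairs$replicate, , drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    tot <- colSums(both)
    conc <- colSums(both & (a == b), na.rm = TRUE)
    repeatability <- ifelse(tot > 0, conc / tot, NA_real_)
  }
  tibble::tibble(locus = colnames(s),
                 clone_id = G$loci$clone_id,
                 call_rate = unname(call_rate),
                 maf = unname(maf),
                 pic = unname(pic),
                 obs_het = unname(obs_het),
                 repeatability = unname(repeatability),
                 monomorphic = unname(maf == 0))
}
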