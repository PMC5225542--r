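# Per-population, per-locus sufficient statistics: called sample sizes,
# alternate-allele frequencies and heterozygote fractions.
pop_locus_sums <- function(G, map, pops = NULL) {
  f <- map_factor(G, map)
  if (!is.null(pops)) {
    keep <- f %in% pops
    G <- geno_subset(G, ind = keep)
    f <- droplevels(factor(f[keep], levels = pops))
  }
  d <- geno_dosage(G)
  called <- !is.na(d)
  dm <- d; dm[!called] <- 0L
  het <- G$scores == 2L; het[!called] <- FALSE
  g <- as.integer(f)
  list(n = rowsum(called + 0, g),          # pops x loci called counts
       alt = rowsum(dm, g),                # alternate allele-copy sums / 2? no: dosage sums
       het = rowsum(het + 0, g),
       pops = levels(f), loci = colnames(G$scores))
}

# Weir & Cockerham (1984) variance components a (among populations),
# b (among individuals within populations), c (within individuals),
# per locus, from per-population sums. Loci informative in fewer than two
# populations yield NA components.
wc_abc <- function(sums) {
  n <- sums$n                      # pops x loci
  used <- n > 0
  r <- colSums(used)
  nsum <- colSums(n)
  p <- sums$alt / (2 * n); p[!used] <- 0
  h <- sums$het / n; h[!used] <- 0
  nbar <- nsum / r
  nc <- (nsum - colSums(n^2) / nsum) / pmax(r - 1, 1)
  pbar <- colSums(sums$alt) / (2 * nsum)
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / (pmax(r - 1, 1) * nbar)
  hbar <- colSums(sums$het) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  bad <- r < 2 | nbar <= 1 | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  tibble::tibble(locus = sums$loci, a = a, b = b, c = cc,
                 pbar = pbar, n_pops = r)
}

#' Multilocus Weir-Cockerham theta
#'
#' theta is computed as the ratio of summed variance components,
#' sum(a) / sum(a + b + c), across all usable loci.
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param pops Optional subset of population labels.
#' @return A single numeric theta estimate.
#' @export
wc_theta <- function(G, map, pops = NULL) {
  comp <- wc_abc(pop_locus_sums(G, map, pops))
  sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
}

#' Per-locus theta and expected heterozygosity
#'
#' Inputs to the outlier scan: for each polymorphic locus across the
#' supplied populations, the Weir-Cockerham theta and the dataset
#' expected heterozygosity He = 2 p q at the weighted mean allele
#' frequency. Monomorphic loci are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @inheritParams wc_theta
#' @return A tibble `locus`, `he`, `theta`.
#' @export
locus_fst_he <- function(G, map, pops = NULL) {
  comp <- wc_abc(pop_locus_sums(G, map, pops))
  mono <- comp$pbar <= 0 | comp$pbar >= 1 | is.na(comp$a)
  out <- tibble::tibble(locus = comp$locus,
                        he = 2 * comp$pbar * (1 - comp$pbar),
                        theta = comp$a / (comp$a + comp$b + comp$c))[!mono, ]
  attr(out, "excluded") <- comp$locus[mono]
  out
}

# theta for exactly two groups from precomputed sums; every argument is a
# loci x k matrix (k permutations evaluated at once). Returns a length-k
# vector of multilocus theta values.
theta_two_groups <- function(n1, alt1, het1, n2, alt2, het2) {
  ok <- n1 > 0 & n2 > 0
  nsum <- n1 + n2
  nbar <- nsum / 2
  nc <- nsum - (n1^2 + n2^2) / nsum
  p1 <- ifelse(n1 > 0, alt1 / (2 * n1), 0)
  p2 <- ifelse(n2 > 0, alt2 / (2 * n2), 0)
  pbar <- (alt1 + alt2) / (2 * nsum)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (het1 + het2) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA; b[!ok] <- NA; cc[!ok] <- NA
  colSums2 <- function(m) if (is.matrix(m)) colSums(m, na.rm = TRUE) else sum(m, na.rm = TRUE)
  colSums2(a) / colSums2(a + b + cc)
}

#' Pairwise Weir-Cockerham FST matrix with permutation p-values
#'
#' For every population pair the multilocus theta is computed, and its
#' significance assessed by shuffling individuals between the two
#' populations: p = fraction of permuted datasets with theta at least the
#' observed value (computed with the +1 correction so p is never 0).
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param n_perm Permutations per pair (0 skips p-values).
#' @param seed Integer seed.
#' @return An object of class `pairwise_matrix` (list with `labels`,
#'   `values` -- the symmetric theta matrix -- and `p_values`). Pairs with
#'   fewer than two individuals in either member are skipped with a
#'   warning (`NA` entries).
#' @export
pairwise_fst <- function(G, map, n_perm = 999, seed = 1L) {
  set.seed(seed)
  f <- map_factor(G, map)
  pops <- levels(f)
  if (length(pops) < 2) stop("need at least two populations", call. = FALSE)
  d <- geno_dosage(G)
  called <- !is.na(d)
  dm <- d; dm[!called] <- 0L
  het <- (G$scores == 2L) & called
  theta <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
  diag(theta) <- 0
  pmat <- theta
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      si <- which(f == pops[i]); sj <- which(f == pops[j])
      if (length(si) < 2 || length(sj) < 2) {
        warning("pair ", pops[i], "-", pops[j], " skipped: fewer than 2 individuals")
        next
      }
      idx <- c(si, sj)
      tcalled <- t(called[idx, , drop = FALSE])
      tdm <- t(dm[idx, , drop = FALSE])
      thet <- t(het[idx, , drop = FALSE])
      memb <- matrix(0, length(idx), 1 + n_perm)
      memb[seq_along(si), 1] <- 1
      if (n_perm > 0) {
        for (k in seq_len(n_perm)) {
          memb[sample.int(length(idx), length(si)), k + 1] <- 1
        }
      }
      n1 <- tcalled %*% memb; alt1 <- tdm %*% memb; h1 <- thet %*% memb
      n2 <- rowSums(tcalled) - n1
      alt2 <- rowSums(tdm) - alt1
      h2 <- rowSums(thet) - h1
      th <- theta_two_groups(n1, alt1, h1, n2, alt2, h2)
      theta[i, j] <- theta[j, i] <- th[1]
      if (n_perm > 0) {
        pmat[i, j] <- pmat[j, i] <-
          (1 + sum(th[-1] >= th[1] - 1e-12)) / (n_perm + 1)
      }
    }
  }
  structure(list(labels = pops, values = theta,
                 p_values = if (n_perm > 0) pmat else NULL,
                 statistic = "wc_theta", n_perm = n_perm),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix> %s over %d populations\n",
              x$statistic, length(x$labels)))
  print(round(x$values, 4))
  invisible(x)
}

#' Per-population Weir-Cockerham inbreeding coefficient
#'
#' The within-population f, multilocus as 1 - sum(c) / sum(b + c) over the
#' single-population variance components (b: among individuals, c: within
#' individuals). A population monomorphic at every locus returns `NA`.
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @return A tibble `population`, `n`, `fis`.
#' @export
fis_wc <- function(G, map) {
  f <- map_factor(G, map)
  purrr::map_dfr(levels(f), function(p) {
    s <- G$scores[f == p, , drop = FALSE]
    d <- geno_dosage(geno_matrix(s))
    n <- colSums(!is.na(d))
    use <- n >= 2
    pfreq <- colSums(d, na.rm = TRUE)[use] / (2 * n[use])
    h <- colSums(s == 2L, na.rm = TRUE)[use] / n[use]
    nn <- n[use]
    b <- nn / (nn - 1) * (pfreq * (1 - pfreq) - (2 * nn - 1) / (4 * nn) * h)
    cc <- h / 2
    denom <- sum(b + cc)
    tibble::tibble(population = p, n = sum(f == p),
                   fis = if (denom > 0) 1 - sum(cc) / denom else NA_real_)
  })
}
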