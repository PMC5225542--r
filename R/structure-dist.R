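#' Nei's (1978) unbiased standard genetic distance
#'
#' DS = -ln(I) with I the normalised identity of genes,
#' I = Jxy / sqrt(Jx Jy), where the within-population homozygosity terms
#' are the unbiased estimators (2n sum(x_i^2) - 1) / (2n - 1) averaged
#' over loci and Jxy = sum(x_i y_i) averaged over loci. Loci with calls
#' in both populations enter the averages.
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @return A `pairwise_matrix` of DS values (no p-values). Pathological
#'   pairs with non-positive identity get `Inf` with a warning.
#' @export
nei_ds <- function(G, map) {
  sums <- pop_locus_sums(G, map)
  n <- sums$n
  p <- sums$alt / (2 * n)
  pops <- sums$pops
  ds <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1):length(pops)) {
      use <- n[i, ] > 0 & n[j, ] > 0
      xi <- p[i, use]; yj <- p[j, use]
      ni <- n[i, use]; nj <- n[j, use]
      jx <- mean((2 * ni * (xi^2 + (1 - xi)^2) - 1) / (2 * ni - 1))
      jy <- mean((2 * nj * (yj^2 + (1 - yj)^2) - 1) / (2 * nj - 1))
      jxy <- mean(xi * yj + (1 - xi) * (1 - yj))
      I <- jxy / sqrt(jx * jy)
      if (!is.finite(I) || I <= 0) {
        warning("non-positive genetic identity for pair ", pops[i], "-", pops[j])
        ds[i, j] <- ds[j, i] <- Inf
      } else {
        ds[i, j] <- ds[j, i] <- -log(min(I, 1))
      }
    }
  }
  structure(list(labels = pops, values = ds, p_values = NULL,
                 statistic = "nei_ds", n_perm = 0),
            class = "pairwise_matrix")
}

#' One minus the proportion of shared alleles
#'
#' Individual-level genetic distance
#' d(i, j) = 1 - shared alleles / (2 x shared typed loci); per locus two
#' identical genotypes share 2 alleles, a heterozygote shares 1 with
#' either homozygote, and opposite homozygotes share 0.
#'
#' @param G A [geno_matrix()].
#' @return A symmetric individuals x individuals distance matrix; pairs
#'   with no shared typed locus are `NA` and flagged with a warning.
#' @export
one_minus_psa <- function(G) {
  d <- geno_dosage(G)
  m <- !is.na(d)
  dm <- d; dm[!m] <- 0L
  a0 <- (dm == 0L) & m
  a2 <- dm == 2L
  msum <- tcrossprod(m + 0)                       # shared typed loci
  sq <- tcrossprod(dm^2, m + 0)
  cross <- tcrossprod(dm)
  diff2 <- sq + t(sq) - 2 * cross                  # sum (di - dj)^2
  n22 <- tcrossprod(a0 + 0, a2 + 0)
  absdiff <- diff2 - 2 * (n22 + t(n22))            # sum |di - dj|
  out <- absdiff / (2 * msum)
  if (any(msum == 0 & upper.tri(msum))) {
    warning("individual pairs with no shared typed locus: distance NA")
    out[msum == 0] <- NA_real_
  }
  diag(out) <- 0
  dimnames(out) <- list(individuals(G), individuals(G))
  out
}

#' Tidy a pairwise matrix
#'
#' @param x A `pairwise_matrix`.
#' @param ... Unused.
#' @return A long tibble `pop_a`, `pop_b`, `value` (and `p_value` when
#'   permutations were run), one row per unordered pair.
#' @export
tidy.pairwise_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  out <- tibble::tibble(pop_a = x$labels[idx[, 1]],
                        pop_b = x$labels[idx[, 2]],
                        value = x$values[idx])
  if (!is.null(x$p_values)) out$p_value <- x$p_values[idx]
  out
}

#' Range summaries over subsets of a pairwise matrix
#'
#' Helper for reporting the extremes of a printed or computed pairwise
#' matrix over declared population subsets (e.g. the maximum
#' differentiation among one ocean basin's populations, or the minimum
#' between two basins).
#'
#' @param x A `pairwise_matrix` or a plain symmetric labelled matrix.
#' @param pops_a Labels of the first subset.
#' @param pops_b Optional labels of the second subset; when omitted the
#'   summary runs over pairs within `pops_a`.
#' @return A tibble with `min`, `max` and the pair labels attaining them.
#' @export
pairwise_range <- function(x, pops_a, pops_b = NULL) {
  v <- if (inherits(x, "pairwise_matrix")) x$values else x
  if (is.null(pops_b)) {
    sub <- v[pops_a, pops_a, drop = FALSE]
    idx <- which(upper.tri(sub), arr.ind = TRUE)
    vals <- sub[upper.tri(sub)]
    la <- rownames(sub)[idx[, 1]]; lb <- colnames(sub)[idx[, 2]]
  } else {
    sub <- v[pops_a, pops_b, drop = FALSE]
    vals <- as.vector(sub)
    la <- rep(rownames(sub), times = ncol(sub))
    lb <- rep(colnames(sub), each = nrow(sub))
  }
  i_min <- which.min(vals); i_max <- which.max(vals)
  tibble::tibble(min = vals[i_min], min_pair = paste(la[i_min], lb[i_min], sep = "-"),
                 max = vals[i_max], max_pair = paste(la[i_max], lb[i_max], sep = "-"))
}

#' Read a combined pairwise FST / DS table
#'
#' Reads a CSV holding a square population table with Weir-Cockerham FST
#' below the diagonal and Nei's DS above it (the layout used for
#' published pairwise tables), returning the two symmetric matrices.
#'
#' @param path CSV path; first column population labels, remaining
#'   columns one per population in the same order.
#' @return A list with `fst` and `ds`, both `pairwise_matrix` objects.
#' @export
read_pairwise_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  labels <- raw[[1]]
  m <- as.matrix(raw[, -1])
  rownames(m) <- labels
  stopifnot(identical(colnames(m), as.character(labels)))
  fst <- m; fst[upper.tri(fst)] <- t(fst)[upper.tri(fst)]
  ds <- m; ds[lower.tri(ds)] <- t(ds)[lower.tri(ds)]
  diag(fst) <- 0; diag(ds) <- 0
  list(fst = structure(list(labels = labels, values = fst, p_values = NULL,
                            statistic = "wc_theta", n_perm = 0),
                       class = "pairwise_matrix"),
       ds = structure(list(labels = labels, values = ds, p_values = NULL,
                           statistic = "nei_ds", n_perm = 0),
                      class = "pairwise_matrix"))
}
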