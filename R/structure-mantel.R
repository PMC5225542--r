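#' Mantel test between two distance matrices
#'
#' Pearson correlation over the off-diagonal pairs, with significance
#' from joint row/column permutation of the second matrix:
#' p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1). With
#' `exhaustive = TRUE` all n! label permutations are enumerated instead
#' and the p-value is exact.
#'
#' @param m1,m2 Symmetric matrices with identical labels (matrix order is
#'   used when labels are absent).
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all permutations (feasible for <= 7 labels).
#' @return A list with `r`, `r_squared`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999, seed = 1L, exhaustive = FALSE) {
  stopifnot(is.matrix(m1), is.matrix(m2), all(dim(m1) == dim(m2)),
            nrow(m1) >= 4)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  lt <- lower.tri(m1)
  x <- m1[lt]
  if (stats::sd(x) == 0 || stats::sd(m2[lt]) == 0) {
    stop("constant distance matrix: Mantel r undefined", call. = FALSE)
  }
  r_obs <- stats::cor(x, m2[lt])
  if (exhaustive) {
    perms <- all_permutations(n)
    rs <- vapply(seq_len(ncol(perms)), function(k) {
      pm <- perms[, k]
      stats::cor(x, m2[pm, pm][lt])
    }, numeric(1))
    p <- sum(rs >= r_obs - 1e-12) / ncol(perms)
    n_used <- ncol(perms)
  } else {
    set.seed(seed)
    rs <- vapply(seq_len(n_perm), function(k) {
      pm <- sample.int(n)
      stats::cor(x, m2[pm, pm][lt])
    }, numeric(1))
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  list(r = r_obs, r_squared = r_obs^2, p_value = p, n_perm = n_used)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (k in seq_len(ncol(sub))) {
    for (pos in seq_len(n)) {
      col <- col + 1L
      out[, col] <- append(sub[, k], n, after = pos - 1)
    }
  }
  out
}
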