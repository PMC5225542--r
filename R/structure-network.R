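#' Mutual k-nearest-neighbour network
#'
#' Builds the fine-scale population-structure graph: an edge joins
#' individuals i and j iff j is among i's k nearest neighbours AND i is
#' among j's (distance ties broken towards the lower index). Edge weight
#' is the genetic distance. Connected components correspond to discrete
#' genetic clusters.
#'
#' @param D Symmetric individual distance matrix (e.g. [one_minus_psa()]).
#' @param k Neighbourhood size, `1 <= k < N`.
#' @return An `igraph` graph with vertex attribute `component`; the
#'   adjacency used is available via `igraph::as_adjacency_matrix`.
#' @export
mutual_knn_network <- function(D, k) {
  n <- nrow(D)
  stopifnot(k >= 1, k < n)
  knn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i])            # ties -> lower index (stable order)
    nb <- seq_len(n)[-i][ord][seq_len(k)]
    knn[i, nb] <- TRUE
  }
  adj <- knn & t(knn)
  w <- D * adj
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  # weighted=TRUE drops zero-distance edges; restore them explicitly
  zero_edges <- which(adj & D == 0 & upper.tri(adj), arr.ind = TRUE)
  if (nrow(zero_edges) > 0) {
    g <- igraph::add_edges(g, t(zero_edges), weight = 0)
  }
  if (!is.null(rownames(D))) igraph::V(g)$name <- rownames(D)
  comp <- igraph::components(g)
  igraph::V(g)$component <- comp$membership
  attr(g, "n_components") <- comp$no
  g
}

# Nei GST between two sets of allele-frequency vectors (biallelic),
# multilocus via summed heterozygosities.
gst_pool <- function(p_a, p_b) {
  hs <- (2 * p_a * (1 - p_a) + 2 * p_b * (1 - p_b)) / 2
  pm <- (p_a + p_b) / 2
  ht <- 2 * pm * (1 - pm)
  (sum(ht) - sum(hs)) / sum(ht)
}

#' Directional relative migration network
#'
#' For each ordered population pair, a hypothetical pooled population
#' (the unweighted mean of the pair's allele frequencies) is constructed;
#' the Nei GST of the receiving population against the pool is converted
#' to a directional relative-migration value (a population receiving many
#' migrants resembles the pool, so its GST against the pool is small and
#' the inbound migration estimate large). The matrix is normalised so its
#' maximum entry is 1. Optional bootstrap over individuals within
#' populations flags pairs whose inbound/outbound asymmetry interval
#' excludes zero.
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param n_boot Bootstrap replicates (0 skips significance flags).
#' @param seed Integer seed.
#' @param conf Confidence level of the asymmetry interval.
#' @return An object of class `migration_network`: list with `m`
#'   (directed relative-migration matrix, `m[a, b]` is a -> b), and
#'   `significant` (logical matrix or `NULL`).
#' @export
directional_migration <- function(G, map, n_boot = 0, seed = 1L, conf = 0.95) {
  set.seed(seed)
  f <- map_factor(G, map)
  if (any(table(f) < 2)) stop("population with fewer than 2 individuals",
                              call. = FALSE)
  pops <- levels(f)
  d <- geno_dosage(G)
  mig_from_freqs <- function(freqs, use) {
    k <- length(pops)
    m <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b) next
      sel <- use[, a] & use[, b]
      pa <- freqs[sel, a]; pb <- freqs[sel, b]
      pool <- (pa + pb) / 2
      g_b <- gst_pool(freqs[sel, b], pool)
      m[a, b] <- if (is.finite(g_b) && g_b > 1e-8) (1 / g_b - 1) / 4 else NA
    }
    finite_max <- max(m, na.rm = TRUE)
    m[is.na(m)] <- finite_max          # indistinguishable-from-pool pairs
    diag(m) <- NA
    m / max(m, na.rm = TRUE)
  }
  pop_freqs <- function(rows_by_pop) {
    fr <- vapply(rows_by_pop, function(rows) {
      dd <- d[rows, , drop = FALSE]
      n <- colSums(!is.na(dd))
      ifelse(n > 0, colSums(dd, na.rm = TRUE) / (2 * n), NA_real_)
    }, numeric(ncol(d)))
    list(freqs = fr, use = !is.na(fr))
  }
  rows0 <- lapply(pops, function(p) which(f == p))
  fr0 <- pop_freqs(rows0)
  m_obs <- mig_from_freqs(fr0$freqs, fr0$use)
  significant <- NULL
  if (n_boot > 0) {
    k <- length(pops)
    asym <- array(NA_real_, c(k, k, n_boot))
    for (b in seq_len(n_boot)) {
      rows_b <- lapply(rows0, function(r) sample(r, length(r), replace = TRUE))
      frb <- pop_freqs(rows_b)
      mb <- mig_from_freqs(frb$freqs, frb$use)
      asym[, , b] <- mb - t(mb)
    }
    alpha <- (1 - conf) / 2
    lo <- apply(asym, c(1, 2), stats::quantile, probs = alpha, na.rm = TRUE)
    hi <- apply(asym, c(1, 2), stats::quantile, probs = 1 - alpha, na.rm = TRUE)
    significant <- lo > 0 | hi < 0
    diag(significant) <- NA
  }
  structure(list(m = m_obs, significant = significant, n_boot = n_boot),
            class = "migration_network")
}

#' @export
print.migration_network <- function(x, ...) {
  cat("<migration_network> relative directional migration (row -> column)\n")
  print(round(x$m, 3))
  invisible(x)
}
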