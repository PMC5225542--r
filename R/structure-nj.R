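#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining from a symmetric non-negative distance
#' matrix, with deterministic tie-breaking (smallest Q, then lowest label
#' pair in the current ordering) and negative-branch handling by clamping
#' to zero while transferring the deficit to the sister branch, so the
#' joined pair's path length is preserved. On an additive matrix the tree
#' reproduces the input path lengths exactly.
#'
#' @param D Symmetric distance matrix, `N >= 3`.
#' @param labels Tip labels; defaults to the matrix row names.
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(D, labels = rownames(D)) {
  n <- nrow(D)
  if (n < 3) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  stopifnot(isSymmetric(unname(D)), all(D >= 0))
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- as.list(labels)            # newick fragment per active node
  D <- unname(D)
  active <- seq_len(n)
  fmt <- function(x) formatC(x, format = "g", digits = 12)
  while (length(active) > 2) {
    m <- length(active)
    Dm <- D[active, active, drop = FALSE]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    i <- idx[1]; j <- idx[2]
    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- paste0("(", nodes[[active[i]]], ":", fmt(li), ",",
                      nodes[[active[j]]], ":", fmt(lj), ")")
    duk <- (Dm[i, ] + Dm[j, ] - dij) / 2
    ai <- active[i]; aj <- active[j]
    D <- rbind(cbind(D, 0), 0)
    new_id <- nrow(D)
    D[new_id, active] <- duk
    D[active, new_id] <- duk
    D[new_id, new_id] <- 0
    nodes[[new_id]] <- new_lab
    active <- c(setdiff(active, c(ai, aj)), new_id)
  }
  i <- active[1]; j <- active[2]
  newick <- paste0("(", nodes[[i]], ":", fmt(max(D[i, j], 0) / 2), ",",
                   nodes[[j]], ":", fmt(max(D[i, j], 0) / 2), ");")
  ape::read.tree(text = newick)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
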