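# Small in-code fixtures shared across tests.

# geno_matrix from a plain score matrix given as rows = individuals.
make_geno <- function(scores, clone_id = NULL, repeatability = NULL) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores))) rownames(scores) <- paste0("i", seq_len(nrow(scores)))
  if (is.null(colnames(scores))) colnames(scores) <- paste0("L", seq_len(ncol(scores)))
  loci <- tibble::tibble(locus = colnames(scores),
                         clone_id = clone_id %||% NA_character_,
                         repeatability = repeatability %||% NA_real_)
  geno_matrix(scores, loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# DArT coding from alternate-allele dosage (test-local copy)
dart_from_dosage <- function(d) {
  s <- d
  s[d == 2] <- 1L
  s[d == 1] <- 2L
  s
}

# Balding-Nichols draw and HW genotype dosages (test-local oracles)
pearl_bn <- function(p, f) {
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}
sim_pop <- function(n, p) {
  matrix(stats::rbinom(n * length(p), 2, rep(p, each = n)), n,
         byrow = FALSE)
}

# two-population map over the rows of a geno_matrix
two_pop_map <- function(G, n1, regions = c("r1", "r1")) {
  ids <- individuals(G)
  pop_map(ids, rep(c("A", "B"), c(n1, length(ids) - n1)),
          rep(regions, c(n1, length(ids) - n1)))
}

# flat (single-region) island-model config for fast simulations
flat_cfg <- function(n_pops = 2, n_per_pop = 50, n_loci = 500, fst = 0.05,
                     fis = 0, seed = 42L, ...) {
  genotype_sim_config(n_regions = 1, pops_per_region = n_pops,
                      n_per_pop = n_per_pop, n_loci = n_loci,
                      fst_between_regions = 0, fst_within_region = fst,
                      fis = fis, missing_rate = 0, clone_duplicate_rate = 0,
                      n_directional_outliers = 0, n_balancing_outliers = 0,
                      replicate_fraction = 0, genotyping_error_rate = 0,
                      seed = seed, ...)
}
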