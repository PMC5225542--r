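# Core 4-level nested sums of squares for one grouping, vectorised over
# loci. Returns summed variance components across loci (per-locus
# coefficient solve, ratio-of-sums reporting).
amova_components <- function(d, het, pop, region) {
  m <- !is.na(d)
  dm <- d; dm[!m] <- 0L
  pops <- levels(pop)
  regions <- levels(region)
  pop_region <- region[match(pops, pop)]
  gi <- as.integer(pop)

  # gene-copy counts and allele-frequency sums per population
  S_p <- rowsum(dm, gi)                     # pops x loci allele-copy sums
  N_p <- 2 * rowsum(m + 0, gi)              # gene copies per pop
  I_p <- rowsum(m + 0, gi)                  # called individuals per pop
  gr <- as.integer(pop_region)
  S_g <- rowsum(S_p, gr)
  N_g <- rowsum(N_p, gr)
  S <- colSums(S_p); N <- colSums(N_p)

  ybar_p <- ifelse(N_p > 0, S_p / N_p, 0)
  ybar_g <- ifelse(N_g > 0, S_g / N_g, 0)
  ybar <- ifelse(N > 0, S / N, 0)

  ss_wi <- 0.5 * colSums(het & m)                     # within individuals
  sum_ci_yi2 <- colSums(dm^2) / 2                      # sum c_i ybar_i^2
  sum_p <- colSums(N_p * ybar_p^2)
  sum_g <- colSums(N_g * ybar_g^2)
  ss_ai <- sum_ci_yi2 - sum_p
  ss_ap <- sum_p - sum_g
  ss_ag <- sum_g - N * ybar^2

  I_tot <- colSums(I_p)                                # called individuals
  P_l <- colSums(N_p > 0)                              # pops with data
  G_l <- colSums(N_g > 0)                              # regions with data
  df_wi <- I_tot
  df_ai <- I_tot - P_l
  df_ap <- P_l - G_l
  df_ag <- G_l - 1

  # unbalanced-design coefficients on gene-copy counts
  sum_np2_ng <- colSums(rowsum(N_p^2, gr) / ifelse(N_g > 0, N_g, 1))
  n1 <- (N - sum_np2_ng) / pmax(df_ap, 1)
  n2 <- (sum_np2_ng - colSums(N_p^2) / N) / pmax(df_ag, 1)
  n3 <- (N - colSums(N_g^2) / N) / pmax(df_ag, 1)

  ms_wi <- ss_wi / pmax(df_wi, 1)
  ms_ai <- ss_ai / pmax(df_ai, 1)
  ms_ap <- ss_ap / pmax(df_ap, 1)
  ms_ag <- ss_ag / pmax(df_ag, 1)

  s4 <- ms_wi
  s3 <- (ms_ai - s4) / 2
  s2 <- ifelse(n1 > 0, (ms_ap - s4 - 2 * s3) / n1, NA)
  s1 <- ifelse(n3 > 0, (ms_ag - s4 - 2 * s3 - n2 * s2) / n3, NA)
  usable <- df_ai > 0 & df_ap > 0 & df_ag > 0 & n1 > 0 & n3 > 0
  c(ag = sum(s1[usable]), ap = sum(s2[usable]),
    ai = sum(s3[usable]), wi = sum(s4[usable]))
}

#' Hierarchical analysis of molecular variance
#'
#' Four-level nested AMOVA on allele-level distances (counts of differing
#' alleles between genotypes, summed over loci): among regions, among
#' populations within regions, among individuals within populations, and
#' within individuals. Variance components follow the standard nested
#' expectations with unbalanced-design coefficients, estimated per locus
#' and summed; components may be negative and are reported as computed.
#' Permutation p-values use level-appropriate schemes: whole populations
#' permuted among regions (among-region component), individuals permuted
#' among populations within their region (among-population component),
#' and alleles permuted among individuals within populations
#' (among-individual component).
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()] with at least two regions.
#' @param n_perm Permutations per level (0 skips p-values).
#' @param seed Integer seed.
#' @return An object of class `amova`: a list with `table` (tibble of
#'   level, sigma2, percent), `phi` (tibble of Phi statistics) and
#'   `p_values`.
#' @export
hierarchical_amova <- function(G, map, n_perm = 99, seed = 1L) {
  set.seed(seed)
  pop <- map_factor(G, map)
  region <- map_factor(G, map, "region")
  if (nlevels(region) < 2) stop("need at least two regions", call. = FALSE)
  if (any(table(region) < 2)) stop("region with a single individual", call. = FALSE)
  d <- geno_dosage(G)
  het <- G$scores == 2L
  obs <- amova_components(d, het, pop, region)
  tot <- sum(obs)
  pct <- 100 * obs / tot
  phi <- tibble::tibble(
    statistic = c("phi_CT", "phi_SC", "phi_ST", "phi_IS", "phi_IT"),
    value = c(obs["ag"] / tot,
              obs["ap"] / (obs["ap"] + obs["ai"] + obs["wi"]),
              (obs["ag"] + obs["ap"]) / tot,
              obs["ai"] / (obs["ai"] + obs["wi"]),
              (obs["ag"] + obs["ap"] + obs["ai"]) / tot))
  p_values <- NULL
  if (n_perm > 0) {
    pops <- levels(pop)
    pop_region <- region[match(pops, pop)]
    hits <- c(ag = 0L, ap = 0L, ai = 0L)
    for (b in seq_len(n_perm)) {
      # regions: permute population labels across regions
      perm_pr <- sample(pop_region)
      reg1 <- factor(perm_pr[as.integer(pop)], levels = levels(region))
      c1 <- amova_components(d, het, pop, reg1)
      if (c1["ag"] >= obs["ag"] - 1e-12) hits["ag"] <- hits["ag"] + 1L
      # populations: permute individuals among pops within regions
      pop2 <- pop
      for (r in levels(region)) {
        sel <- which(region == r)
        pop2[sel] <- pop[sel][sample.int(length(sel))]
      }
      c2 <- amova_components(d, het, pop2, region)
      if (c2["ap"] >= obs["ap"] - 1e-12) hits["ap"] <- hits["ap"] + 1L
      # individuals: re-pair alleles among individuals within populations
      d3 <- d
      for (p in levels(pop)) {
        sel <- which(pop == p)
        d3[sel, ] <- shuffle_alleles(d[sel, , drop = FALSE])
      }
      het3 <- d3 == 1L
      c3 <- amova_components(d3, het3, pop, region)
      if (c3["ai"] >= obs["ai"] - 1e-12) hits["ai"] <- hits["ai"] + 1L
    }
    p_values <- tibble::tibble(
      level = c("among_regions", "among_populations", "among_individuals"),
      p_value = as.numeric((1 + hits) / (n_perm + 1)))
  }
  structure(list(
    table = tibble::tibble(
      level = c("among_regions", "among_populations_within_regions",
                "among_individuals_within_populations", "within_individuals"),
      sigma2 = as.numeric(obs), percent = as.numeric(pct)),
    phi = phi, p_values = p_values, n_perm = n_perm),
    class = "amova")
}

# Randomly re-pair the 2N allele copies of each locus among the N
# individuals of one population (missing genotypes keep their NA).
shuffle_alleles <- function(dblock) {
  n <- nrow(dblock)
  for (l in seq_len(ncol(dblock))) {
    ok <- which(!is.na(dblock[, l]))
    if (length(ok) < 2) next
    alleles <- c(rep(1L, sum(dblock[ok, l])),
                 rep(0L, 2 * length(ok) - sum(dblock[ok, l])))
    alleles <- sample(alleles)
    dblock[ok, l] <- alleles[seq_along(ok) * 2 - 1] + alleles[seq_along(ok) * 2]
  }
  dblock
}

#' @export
print.amova <- function(x, ...) {
  cat("<amova> hierarchical analysis of molecular variance\n")
  print(as.data.frame(x$table))
  invisible(x)
}

#' @export
tidy.amova <- function(x, ...) {
  out <- x$table
  if (!is.null(x$p_values)) {
    out <- dplyr::left_join(out,
      dplyr::mutate(x$p_values,
                    level = dplyr::recode(.data$level,
                      among_populations = "among_populations_within_regions",
                      among_individuals = "among_individuals_within_populations")),
      by = "level")
  }
  out
}

#' @export
glance.amova <- function(x, ...) {
  tibble::tibble(
    pct_among_regions = x$table$percent[1],
    pct_among_populations = x$table$percent[2],
    pct_among_individuals = x$table$percent[3],
    pct_within_individuals = x$table$percent[4],
    phi_ct = x$phi$value[x$phi$statistic == "phi_CT"],
    phi_st = x$phi$value[x$phi$statistic == "phi_ST"])
}
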