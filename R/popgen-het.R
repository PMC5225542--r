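#' Observed and unbiased expected heterozygosity per population
#'
#' Ho is the mean over loci of the heterozygote fraction among non-missing
#' calls; Hnb is the mean over loci of the sample-size-corrected expected
#' heterozygosity (2n/(2n-1)) (1 - p^2 - q^2) with n the number of
#' non-missing individuals at the locus in that population. Loci that are
#' monomorphic dataset-wide contribute zero to both.
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @return A tibble `population`, `n`, `ho`, `ho_sd`, `hnb`, `hnb_sd`.
#' @export
heterozygosities <- function(G, map) {
  f <- map_factor(G, map)
  purrr::map_dfr(levels(f), function(pp) {
    s <- G$scores[f == pp, , drop = FALSE]
    if (nrow(s) < 2) stop("population ", pp, " has fewer than 2 individuals",
                          call. = FALSE)
    d <- geno_dosage(geno_matrix(s))
    n <- colSums(!is.na(d))
    use <- n >= 2
    ho_l <- ifelse(n > 0, colSums(s == 2L, na.rm = TRUE) / n, NA_real_)[use]
    p <- (colSums(d, na.rm = TRUE) / (2 * n))[use]
    nn <- n[use]
    hnb_l <- (2 * nn / (2 * nn - 1)) * (1 - p^2 - (1 - p)^2)
    tibble::tibble(population = pp, n = nrow(s),
                   ho = mean(ho_l), ho_sd = stats::sd(ho_l),
                   hnb = mean(hnb_l), hnb_sd = stats::sd(hnb_l))
  })
}

#' Allelic diversity summaries
#'
#' Per population: A, the mean number of alleles per locus (for biallelic
#' data `1 +` the fraction of loci with both alleles observed in the
#' population) and Ar, the rare allelic richness (fraction of loci whose
#' within-population minor allele frequency lies in (0, 0.05)). Per group
#' (by default the regions of the map): Ap, the number of (locus, allele)
#' pairs observed in exactly one group, optionally rarefied to the
#' smallest group's gene count by hypergeometric expectation.
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param groups Named assignment of populations to groups; default uses
#'   the map's regions.
#' @param rarefy Apply hypergeometric rarefaction to the private-allele
#'   counts (expectation at the smallest group's gene count).
#' @return A list with `populations` (tibble `population`, `a`, `ar`) and
#'   `private_alleles` (tibble `group`, `ap`).
#' @export
allele_summaries <- function(G, map, groups = NULL, rarefy = FALSE) {
  f <- map_factor(G, map)
  d <- geno_dosage(G)
  pops_tbl <- purrr::map_dfr(levels(f), function(pp) {
    dp <- d[f == pp, , drop = FALSE]
    n <- colSums(!is.na(dp))
    alt <- colSums(dp, na.rm = TRUE)
    p <- ifelse(n > 0, alt / (2 * n), 0)
    maf <- pmin(p, 1 - p)
    poly <- maf > 0
    tibble::tibble(population = pp,
                   a = 1 + mean(poly[n > 0]),
                   ar = mean(maf > 0 & maf < 0.05))
  })

  if (is.null(groups)) {
    groups <- stats::setNames(map$region[match(levels(f), map$population)],
                              levels(f))
  }
  if (any(!levels(f) %in% names(groups))) stop("groups must cover all populations",
                                               call. = FALSE)
  glev <- unique(unname(groups[levels(f)]))
  gfac <- factor(unname(groups[as.character(f)]), levels = glev)
  if (any(table(gfac) == 0)) stop("empty group", call. = FALSE)
  # per group allele presence/counts
  counts <- lapply(glev, function(g) {
    dg <- d[gfac == g, , drop = FALSE]
    n2 <- 2 * colSums(!is.na(dg))
    alt <- colSums(dg, na.rm = TRUE)
    cbind(ref = n2 - alt, alt = alt, total = n2)
  })
  names(counts) <- glev
  pres <- lapply(counts, function(cc) cbind(cc[, "ref"] > 0, cc[, "alt"] > 0))
  n_groups_with <- Reduce(`+`, pres)
  if (!rarefy) {
    ap <- vapply(glev, function(g)
      sum(pres[[g]] & n_groups_with == 1), numeric(1))
  } else {
    m <- min(vapply(counts, function(cc) min(cc[, "total"][cc[, "total"] > 0]),
                    numeric(1)))
    p_obs <- lapply(glev, function(g) {
      cc <- counts[[g]]
      sapply(c("ref", "alt"), function(al) {
        x <- cc[, al]; N <- cc[, "total"]
        ifelse(N >= m, 1 - exp(lchoose(N - x, m) - lchoose(N, m)), x > 0)
      })
    })
    names(p_obs) <- glev
    ap <- vapply(glev, function(g) {
      others <- Reduce(`*`, lapply(setdiff(glev, g),
                                   function(h) 1 - p_obs[[h]]))
      sum(p_obs[[g]] * others)
    }, numeric(1))
  }
  list(populations = pops_tbl,
       private_alleles = tibble::tibble(group = glev, ap = unname(ap)))
}

#' Individual multilocus heterozygosity metrics
#'
#' Per individual: MLH (heterozygous / typed loci), HL (homozygosity by
#' locus: the sum of locus information content E_h = 2pq over the
#' homozygous typed loci divided by the sum over all typed loci, with p
#' the population-level frequency), SH (standardised heterozygosity: the
#' heterozygous proportion divided by the mean heterozygosity of the loci
#' the individual is typed at), and IR (internal relatedness,
#' (2H - sum f_i) / (2N - sum f_i) with H the homozygous count, N the
#' typed count and f_i the dataset-wide frequencies of the alleles
#' carried).
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param sh_method Denominator of SH: `"observed"` uses the mean observed
#'   heterozygosity of the typed loci in the individual's population;
#'   `"expected"` uses their mean 2pq.
#' @return A tibble `individual`, `population`, `n_typed`, `mlh`, `hl`,
#'   `sh`, `ir`. Individuals typed at zero loci get all metrics `NA`.
#' @export
individual_heterozygosity <- function(G, map, sh_method = c("observed", "expected")) {
  sh_method <- match.arg(sh_method)
  f <- map_factor(G, map)
  s <- G$scores
  d <- geno_dosage(G)
  called <- !is.na(s)
  # dataset-wide allele frequencies
  n_all <- colSums(called)
  p_all <- ifelse(n_all > 0, colSums(d, na.rm = TRUE) / (2 * n_all), 0)
  out <- vector("list", nlevels(f))
  for (k in seq_len(nlevels(f))) {
    rows <- which(f == levels(f)[k])
    sp <- s[rows, , drop = FALSE]
    dp <- d[rows, , drop = FALSE]
    cp <- called[rows, , drop = FALSE]
    n_pop <- colSums(cp)
    p_pop <- ifelse(n_pop > 0, colSums(dp, na.rm = TRUE) / (2 * n_pop), 0)
    eh <- 2 * p_pop * (1 - p_pop)
    hobs_pop <- ifelse(n_pop > 0, colSums(sp == 2L, na.rm = TRUE) / n_pop, 0)
    het <- (sp == 2L) & cp
    hom <- (sp != 2L) & cp
    n_typed <- rowSums(cp)
    mlh <- ifelse(n_typed > 0, rowSums(het) / n_typed, NA_real_)
    hl_num <- rowSums(sweep(hom + 0, 2, eh, `*`))
    hl_den <- rowSums(sweep(cp + 0, 2, eh, `*`))
    hl <- ifelse(n_typed > 0 & hl_den > 0, hl_num / hl_den, NA_real_)
    mean_h <- if (sh_method == "observed") hobs_pop else eh
    sh_den <- rowSums(sweep(cp + 0, 2, mean_h, `*`)) / pmax(n_typed, 1)
    sh <- ifelse(n_typed > 0 & sh_den > 0, mlh / sh_den, NA_real_)
    # sum of dataset frequencies of the alleles carried: het -> p + q = 1,
    # ref hom -> 2(1-p), alt hom -> 2p
    fsum <- rowSums(het) +
      rowSums(sweep((sp == 0L & cp) + 0, 2, 2 * (1 - p_all), `*`)) +
      rowSums(sweep((sp == 1L & cp) + 0, 2, 2 * p_all, `*`))
    h_count <- rowSums(hom)
    ir <- ifelse(2 * n_typed - fsum != 0 & n_typed > 0,
                 (2 * h_count - fsum) / (2 * n_typed - fsum), NA_real_)
    out[[k]] <- tibble::tibble(individual = rownames(sp),
                               population = levels(f)[k],
                               n_typed = unname(n_typed),
                               mlh = unname(mlh), hl = unname(hl),
                               sh = unname(sh), ir = unname(ir))
  }
  dplyr::bind_rows(out)
}
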