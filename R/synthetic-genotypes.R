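#' Configuration for the hierarchical island-model genotype generator
#'
#' Defaults emulate the study design the package is built around: two ocean
#' basins holding 4 and 10 populations with the per-site sample sizes of
#' the real survey (580 oysters in total), ~11.6k base SNPs carrying enough
#' clone duplicates to reach ~19.7k raw locus columns (41% duplicate loss
#' on de-duplication), 15% of individuals replicated for repeatability
#' scoring, strong inbreeding (F_IS = 0.6) and a between-basin F_ST of
#' 0.18. See the methods vignette for the rationale behind values the
#' study does not pin down.
#'
#' @param n_regions Number of regions (ocean basins).
#' @param pops_per_region Integer vector, populations per region.
#' @param n_per_pop Integer vector of per-population sample sizes, recycled
#'   across populations in order.
#' @param n_loci Number of base (non-duplicate) SNP loci.
#' @param fst_between_regions,fst_within_region Balding-Nichols dispersion
#'   of region frequencies around the ancestral frequency, and of
#'   population frequencies around their region frequency.
#' @param fis Within-population inbreeding coefficient used when drawing
#'   genotypes: P(het) = 2pq(1 - fis).
#' @param missing_rate Per-call missing probability.
#' @param clone_duplicate_rate Fraction of base loci duplicated under a
#'   shared clone id (rate 0.5 on 100 base loci gives 150 columns).
#' @param n_directional_outliers,n_balancing_outliers Counts of planted
#'   outlier loci.
#' @param outlier_fst_multiplier Population-level dispersion multiplier for
#'   directional outliers.
#' @param replicate_fraction Fraction of individuals genotyped twice.
#' @param genotyping_error_rate Per-call discordance probability of a
#'   replicate (and of clone-duplicate columns).
#' @param seed Integer RNG seed.
#' @return A validated list of class `genotype_sim_config`.
#' @export
genotype_sim_config <- function(n_regions = 2,
                                pops_per_region = c(4, 10),
                                n_per_pop = c(50, 49, 35, 20,
                                              24, 47, 48, 35, 38, 50, 61, 28, 45, 50),
                                n_loci = 11587,
                                fst_between_regions = 0.18,
                                fst_within_region = 0.03,
                                fis = 0.6,
                                missing_rate = 0.10,
                                clone_duplicate_rate = 0.697,
                                n_directional_outliers = 100,
                                outlier_fst_multiplier = 5,
                                n_balancing_outliers = 40,
                                replicate_fraction = 0.15,
                                genotyping_error_rate = 0.01,
                                seed = 1L) {
  cfg <- list(n_regions = n_regions, pops_per_region = pops_per_region,
              n_per_pop = n_per_pop, n_loci = n_loci,
              fst_between_regions = fst_between_regions,
              fst_within_region = fst_within_region, fis = fis,
              missing_rate = missing_rate,
              clone_duplicate_rate = clone_duplicate_rate,
              n_directional_outliers = n_directional_outliers,
              outlier_fst_multiplier = outlier_fst_multiplier,
              n_balancing_outliers = n_balancing_outliers,
              replicate_fraction = replicate_fraction,
              genotyping_error_rate = genotyping_error_rate,
              seed = as.integer(seed))
  fr <- c("fst_between_regions", "fst_within_region", "fis", "missing_rate",
          "clone_duplicate_rate", "replicate_fraction", "genotyping_error_rate")
  for (f in fr) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) stop(f, " must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$fst_between_regions >= 1 || cfg$fst_within_region >= 1) {
    stop("fst values must lie in [0, 1)", call. = FALSE)
  }
  if (length(cfg$pops_per_region) != cfg$n_regions) {
    cfg$pops_per_region <- rep_len(cfg$pops_per_region, cfg$n_regions)
  }
  if (cfg$n_directional_outliers + cfg$n_balancing_outliers > cfg$n_loci) {
    stop("more planted outliers than loci", call. = FALSE)
  }
  if (cfg$outlier_fst_multiplier <= 0) stop("outlier_fst_multiplier must be > 0", call. = FALSE)
  structure(cfg, class = "genotype_sim_config")
}

# Balding-Nichols marginal: frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F).
rbeta_bn <- function(p, f) {
  out <- p
  pos <- f > 1e-12
  if (any(pos)) {
    a <- p[pos] * (1 - f[pos]) / f[pos]
    b <- (1 - p[pos]) * (1 - f[pos]) / f[pos]
    out[pos] <- stats::rbeta(sum(pos), a, b)
  }
  out
}

# DArT coding from alternate-allele dosage.
dosage_to_dart <- function(d) {
  s <- d
  s[d == 2L] <- 1L
  s[d == 1L] <- 2L
  s
}

draw_pop_genotypes <- function(n, p, fis) {
  L <- length(p)
  q <- 1 - p
  p_alt2 <- p^2 + fis * p * q
  p_het <- 2 * p * q * (1 - fis)
  r <- matrix(stats::runif(n * L), n, L)
  d <- matrix(0L, n, L)
  d[r < rep(p_alt2, each = n)] <- 2L
  d[r >= rep(p_alt2, each = n) & r < rep(p_alt2 + p_het, each = n)] <- 1L
  d
}

study_site_coords <- function() {
  tibble::tibble(
    population = c("abrolhos", "iran", "tan_mafia", "tan_mtwara",
                   "taiwan", "vietnam", "indonesia", "gbr", "png",
                   "solomon", "fiji", "tonga", "cook", "frpoly"),
    lat = c(-28.7, 26.7, -7.9, -10.3, 22.1, 12.2, 1.5, -18.3, -2.6,
            -8.1, -18.0, -21.2, -10.4, -15.5),
    lon = c(113.8, 53.6, 39.7, 40.2, 120.7, 109.2, 124.8, 147.7, 150.8,
            156.8, 178.5, -175.2, -161.0, -146.8))
}

#' Simulate a hierarchical island-model SNP dataset
#'
#' Draws, per base locus, an ancestral frequency uniform on `[0.05, 0.95]`,
#' region frequencies from a Balding-Nichols beta around it, and population
#' frequencies likewise around the region value; directional outlier loci
#' use a multiplied population-level dispersion and balancing outliers a
#' near-zero dispersion at both levels. Genotypes are drawn with
#' inbreeding, then missing calls, clone-duplicate locus columns and
#' replicated individuals (with genotyping error) are injected.
#'
#' @param cfg A [genotype_sim_config()].
#' @return A list with elements `genotypes` (a [geno_matrix()] whose locus
#'   table carries clone ids and replicate-based repeatability), `map`
#'   (a [pop_map()] with site coordinates), `replicate_pairs` (tibble of
#'   replicate individual id pairs) and `truth` (per-locus ancestral
#'   frequencies, outlier labels, clone groupings and the per-population
#'   frequency matrix).
#' @export
simulate_genotypes <- function(cfg = genotype_sim_config()) {
  stopifnot(inherits(cfg, "genotype_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_loci
  n_pops <- sum(cfg$pops_per_region)
  study_layout <- cfg$n_regions == 2 && identical(cfg$pops_per_region, c(4, 10))
  if (study_layout) {
    coords <- study_site_coords()
    pop_names <- coords$population
    region_names <- c("indian", "pacific")
  } else {
    region_names <- paste0("region_", seq_len(cfg$n_regions))
    pop_names <- unlist(lapply(seq_len(cfg$n_regions), function(r)
      paste0("pop_", r, "_", seq_len(cfg$pops_per_region[r]))))
    coords <- tibble::tibble(
      population = pop_names,
      lat = -20 + 5 * unlist(lapply(cfg$pops_per_region, seq_len)),
      lon = 60 + 80 * (rep(seq_len(cfg$n_regions), cfg$pops_per_region) - 1) +
        8 * unlist(lapply(cfg$pops_per_region, seq_len)))
  }
  pop_region <- rep(region_names, cfg$pops_per_region)
  n_per_pop <- rep_len(cfg$n_per_pop, n_pops)

  p_anc <- stats::runif(L, 0.05, 0.95)
  class <- rep("neutral", L)
  idx <- sample.int(L, cfg$n_directional_outliers + cfg$n_balancing_outliers)
  if (cfg$n_directional_outliers > 0)
    class[idx[seq_len(cfg$n_directional_outliers)]] <- "directional"
  if (cfg$n_balancing_outliers > 0)
    class[idx[cfg$n_directional_outliers + seq_len(cfg$n_balancing_outliers)]] <- "balancing"

  eps <- 1e-4
  f_region <- rep(cfg$fst_between_regions, L)
  f_region[class == "balancing"] <- eps
  f_pop <- rep(cfg$fst_within_region, L)
  f_pop[class == "directional"] <-
    pmin(0.95, cfg$fst_within_region * cfg$outlier_fst_multiplier)
  f_pop[class == "balancing"] <- eps

  region_freq <- vapply(seq_len(cfg$n_regions),
                        function(r) rbeta_bn(p_anc, f_region),
                        numeric(L))
  pop_freq <- vapply(seq_len(n_pops),
                     function(k) rbeta_bn(region_freq[, match(pop_region[k], region_names)],
                                          f_pop),
                     numeric(L))
  colnames(pop_freq) <- pop_names

  blocks <- lapply(seq_len(n_pops), function(k)
    draw_pop_genotypes(n_per_pop[k], pop_freq[, k], cfg$fis))
  d <- do.call(rbind, blocks)
  ids <- unlist(lapply(seq_len(n_pops), function(k)
    sprintf("%s_%02d", pop_names[k], seq_len(n_per_pop[k]))))
  rownames(d) <- ids

  # replicated individuals with genotyping error
  n_rep <- round(cfg$replicate_fraction * nrow(d))
  rep_pairs <- tibble::tibble(id = character(), replicate = character())
  if (n_rep > 0) {
    sel <- sort(sample.int(nrow(d), n_rep))
    repd <- d[sel, , drop = FALSE]
    if (cfg$genotyping_error_rate > 0) {
      flip <- matrix(stats::runif(length(repd)) < cfg$genotyping_error_rate,
                     nrow(repd))
      shift <- matrix(sample(1:2, length(repd), replace = TRUE), nrow(repd))
      repd[flip] <- (repd[flip] + shift[flip]) %% 3L
    }
    rep_ids <- paste0(rownames(d)[sel], "_rep")
    rownames(repd) <- rep_ids
    rep_pairs <- tibble::tibble(id = rownames(d)[sel], replicate = rep_ids)
    d <- rbind(d, repd)
  }

  # missing calls
  if (cfg$missing_rate > 0) {
    d[matrix(stats::runif(length(d)) < cfg$missing_rate, nrow(d))] <- NA_integer_
  }

  # clone-duplicate locus columns (extra missingness + error keeps the
  # original column the better-quality member of each clone group)
  locus_names <- sprintf("L%05d", seq_len(L))
  clone_ids <- sprintf("clone%05d", seq_len(L))
  colnames(d) <- locus_names
  n_dup <- round(cfg$clone_duplicate_rate * L)
  if (n_dup > 0) {
    dup_of <- sort(sample.int(L, n_dup))
    dup <- d[, dup_of, drop = FALSE]
    if (cfg$genotyping_error_rate > 0) {
      flip <- matrix(stats::runif(length(dup)) < cfg$genotyping_error_rate, nrow(dup))
      shift <- matrix(sample(1:2, length(dup), replace = TRUE), nrow(dup))
      dup[!is.na(dup) & flip] <- (dup[!is.na(dup) & flip] + shift[!is.na(dup) & flip]) %% 3L
    }
    extra_miss <- max(cfg$missing_rate, 0.02)
    dup[matrix(stats::runif(length(dup)) < extra_miss, nrow(dup))] <- NA_integer_
    colnames(dup) <- sprintf("%s_d", locus_names[dup_of])
    d <- cbind(d, dup)
    clone_ids <- c(clone_ids, clone_ids[dup_of])
    locus_names <- colnames(d)
  }

  scores <- dosage_to_dart(d)
  # replicate-based repeatability per locus (concordant non-missing calls)
  repeatability <- rep(NA_real_, ncol(scores))
  if (nrow(rep_pairs) > 0) {
    a <- scores[rep_pairs$id, , drop = FALSE]
    b <- scores[rep_pairs$replicate, , drop = FALSE]
    both <- !is.na(a) & !is.na(b)
    conc <- colSums(both & (a == b), na.rm = TRUE)
    tot <- colSums(both)
    repeatability <- ifelse(tot > 0, conc / tot, NA_real_)
  }
  loci_tbl <- tibble::tibble(locus = locus_names, clone_id = clone_ids,
                             repeatability = repeatability)
  G <- geno_matrix(scores, loci_tbl)

  all_ids <- rownames(scores)
  base_of <- sub("_rep$", "", all_ids)
  pop_of <- rep(pop_names, n_per_pop)[match(base_of, ids)]
  map <- pop_map(all_ids, pop_of,
                 region_names[match(pop_region[match(pop_of, pop_names)], region_names)],
                 coords)

  truth <- list(
    loci = tibble::tibble(locus = locus_names,
                          clone_id = clone_ids,
                          base_locus = c(rep(TRUE, L), rep(FALSE, length(locus_names) - L)),
                          class = c(class, class[match(clone_ids[-seq_len(L)],
                                                       clone_ids[seq_len(L)])]),
                          p_anc = c(p_anc, p_anc[match(clone_ids[-seq_len(L)],
                                                       clone_ids[seq_len(L)])])),
    pop_freq = pop_freq,
    config = cfg)
  list(genotypes = G, map = map, replicate_pairs = rep_pairs, truth = truth)
}

#' Drop replicate individuals from a genotype matrix
#'
#' Technical replicates exist to score repeatability; population analyses
#' run on the base individuals only.
#'
#' @param G A [geno_matrix()].
#' @param replicate_pairs Tibble with columns `id`, `replicate`.
#' @return A [geno_matrix()] without the replicate rows.
#' @export
drop_replicates <- function(G, replicate_pairs) {
  keep <- setdiff(individuals(G), replicate_pairs$replicate)
  geno_subset(G, ind = keep)
}

#' Forward Wright-Fisher simulation of a single diploid population
#'
#' Unlinked biallelic loci evolve under pure drift in an ideal
#' random-mating population of constant size; background linkage
#' disequilibrium among the unlinked loci at equilibrium carries the
#' 1/(3Ne) signal the LD method of [ne_ld()] estimates.
#'
#' @param ne True effective (census) size of the ideal population.
#' @param n_loci Number of unlinked loci.
#' @param n_gen Generations to evolve (LD equilibrates within ~10).
#' @param sample_size Individuals sampled at the end.
#' @param init_freq_range Range of initial allele frequencies.
#' @return A list with `genotypes` (a [geno_matrix()]) and `map`.
#' @export
simulate_wright_fisher <- function(ne = 100, n_loci = 1000, n_gen = 10,
                                   sample_size = 50,
                                   init_freq_range = c(0.3, 0.7)) {
  p0 <- stats::runif(n_loci, init_freq_range[1], init_freq_range[2])
  a1 <- matrix(stats::rbinom(ne * n_loci, 1, rep(p0, each = ne)), ne, n_loci)
  a2 <- matrix(stats::rbinom(ne * n_loci, 1, rep(p0, each = ne)), ne, n_loci)
  gamete <- function(parent_idx) {
    pick <- matrix(stats::runif(ne * n_loci) < 0.5, ne, n_loci)
    out <- a1[parent_idx, , drop = FALSE]
    alt <- a2[parent_idx, , drop = FALSE]
    out[pick] <- alt[pick]
    out
  }
  for (g in seq_len(n_gen)) {
    mothers <- sample.int(ne, ne, replace = TRUE)
    fathers <- sample.int(ne, ne, replace = TRUE)
    new1 <- gamete(mothers)
    new2 <- gamete(fathers)
    a1 <- new1; a2 <- new2
  }
  sel <- sample.int(ne, sample_size)
  d <- a1[sel, , drop = FALSE] + a2[sel, , drop = FALSE]
  rownames(d) <- sprintf("wf_%03d", seq_len(sample_size))
  colnames(d) <- sprintf("L%04d", seq_len(n_loci))
  G <- geno_matrix(dosage_to_dart(d))
  list(genotypes = G,
       map = pop_map(rownames(d), "wf", "all"))
}
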