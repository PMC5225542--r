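#' Simulate the heterozygosity-conditioned neutral FST cloud
#'
#' FDIST-style island-model null: each simulated locus draws an ancestral
#' frequency uniform on `[0.05, 0.95]`, population frequencies from a
#' Balding-Nichols beta at the target FST, and genotypes at the observed
#' sample sizes; the per-locus Weir-Cockerham theta and dataset expected
#' heterozygosity He are recorded. The beta dispersion is iteratively
#' recalibrated on pilot batches until the realised multilocus theta is
#' within 3% (relative) of the requested mean, so the final cloud tracks
#' the target within the 10% contract.
#'
#' @param mean_fst Target mean theta, in (0, 1).
#' @param n_pops Number of populations.
#' @param sample_sizes Per-population sample sizes (recycled).
#' @param n_sim_loci Loci in the final cloud.
#' @param seed Integer seed.
#' @param fis Within-population inbreeding used when drawing genotypes.
#' @return A tibble `he`, `theta` with attributes `calibrated_f` and
#'   `realised_theta`.
#' @export
simulate_null <- function(mean_fst, n_pops, sample_sizes, n_sim_loci = 50000,
                          seed = 1L, fis = 0) {
  if (mean_fst <= 0 || mean_fst >= 1) stop("mean_fst must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  sample_sizes <- rep_len(sample_sizes, n_pops)
  sim_batch <- function(f, L) {
    p_anc <- stats::runif(L, 0.05, 0.95)
    pf <- vapply(seq_len(n_pops), function(k) rbeta_bn(p_anc, rep(f, L)),
                 numeric(L))
    n <- matrix(rep(sample_sizes, each = L), L, n_pops)
    blocks <- lapply(seq_len(n_pops), function(k)
      draw_pop_genotypes(sample_sizes[k], pf[, k], fis))
    sums <- list(
      n = t(vapply(blocks, function(b) colSums(!is.na(b)), numeric(L))),
      alt = t(vapply(blocks, function(b) colSums(b), numeric(L))),
      het = t(vapply(blocks, function(b) colSums(b == 1L), numeric(L))),
      pops = paste0("p", seq_len(n_pops)), loci = sprintf("sim%06d", seq_len(L)))
    wc_abc(sums)
  }
  f <- mean_fst
  for (it in seq_len(8)) {
    comp <- sim_batch(f, 5000L)
    realised <- sum(comp$a, na.rm = TRUE) /
      sum(comp$a + comp$b + comp$c, na.rm = TRUE)
    if (abs(realised - mean_fst) / mean_fst < 0.03) break
    f <- min(max(f * mean_fst / max(realised, 1e-6), 1e-4), 0.95)
  }
  comp <- sim_batch(f, as.integer(n_sim_loci))
  realised <- sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  keep <- comp$pbar > 0 & comp$pbar < 1 & !is.na(comp$a)
  out <- tibble::tibble(he = 2 * comp$pbar[keep] * (1 - comp$pbar[keep]),
                        theta = (comp$a / (comp$a + comp$b + comp$c))[keep])
  attr(out, "calibrated_f") <- f
  attr(out, "realised_theta") <- realised
  out
}

#' Heterozygosity-banded empirical p-values against a null cloud
#'
#' The null cloud is cut into quantile bins of He; each observed locus is
#' compared with the null loci in its He band:
#' p_directional = (1 + #\{null theta >= observed\}) / (band size + 1),
#' and p_balancing the analogous lower-tail probability.
#'
#' @param observed Tibble with columns `locus`, `he`, `theta`
#'   (from [locus_fst_he()]).
#' @param null_cloud Tibble `he`, `theta` (from [simulate_null()], at
#'   least 10,000 loci recommended).
#' @param n_bins Number of He quantile bands.
#' @return `observed` with `p_directional` and `p_balancing` added.
#' @export
empirical_p <- function(observed, null_cloud, n_bins = 20) {
  edges <- unique(stats::quantile(null_cloud$he, probs = seq(0, 1, length.out = n_bins + 1)))
  band_of <- function(he) {
    b <- findInterval(he, edges, rightmost.closed = TRUE, all.inside = TRUE)
    pmin(pmax(b, 1), length(edges) - 1)
  }
  nb <- band_of(null_cloud$he)
  ob <- band_of(observed$he)
  p_dir <- p_bal <- numeric(nrow(observed))
  for (b in sort(unique(ob))) {
    nt <- sort(null_cloud$theta[nb == b])
    if (!length(nt)) {                      # empty band: nearest occupied
      warning("empty He band ", b, "; using nearest band")
      occupied <- sort(unique(nb))
      nt <- sort(null_cloud$theta[nb == occupied[which.min(abs(occupied - b))]])
    }
    sel <- ob == b
    th <- observed$theta[sel]
    n_ge <- length(nt) - findInterval(th - 1e-12, nt)
    n_le <- findInterval(th + 1e-12, nt)
    p_dir[sel] <- (1 + n_ge) / (length(nt) + 1)
    p_bal[sel] <- (1 + n_le) / (length(nt) + 1)
  }
  observed$p_directional <- p_dir
  observed$p_balancing <- p_bal
  attr(observed, "band_edges") <- edges
  observed
}

#' Classify loci over a false-discovery-rate ladder
#'
#' Benjamini-Hochberg control is applied within each tail separately
#' (directional and balancing) at every ladder level; counts per level
#' are reported and the classification at the working level partitions
#' loci into neutral / directional / balancing (a locus significant in
#' both tails takes the tail with the smaller p-value).
#'
#' @param p Tibble with `locus`, `p_directional`, `p_balancing`
#'   (from [empirical_p()]).
#' @param ladder FDR levels to report.
#' @param working_level Level used for the classification.
#' @return An `outlier_report` tibble: per-locus q-values per tail, the
#'   class, and a `counts` attribute (tibble of detections per ladder
#'   level and tail).
#' @export
fdr_classify <- function(p, ladder = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2),
                         working_level = 0.05) {
  q_dir <- stats::p.adjust(p$p_directional, "BH")
  q_bal <- stats::p.adjust(p$p_balancing, "BH")
  counts <- purrr::map_dfr(ladder, function(l)
    tibble::tibble(fdr = l,
                   directional = sum(q_dir <= l),
                   balancing = sum(q_bal <= l)))
  class <- rep("neutral", nrow(p))
  dir_sig <- q_dir <= working_level
  bal_sig <- q_bal <= working_level
  both <- dir_sig & bal_sig
  class[dir_sig & !both] <- "directional"
  class[bal_sig & !both] <- "balancing"
  class[both] <- ifelse(p$p_directional[both] <= p$p_balancing[both],
                        "directional", "balancing")
  out <- p
  out$q_directional <- q_dir
  out$q_balancing <- q_bal
  out$class <- class
  attr(out, "counts") <- counts
  attr(out, "working_level") <- working_level
  class(out) <- c("outlier_report", class(out))
  out
}

#' @export
glance.outlier_report <- function(x, ...) {
  tibble::tibble(n_loci = nrow(x),
                 n_directional = sum(x$class == "directional"),
                 n_balancing = sum(x$class == "balancing"),
                 n_neutral = sum(x$class == "neutral"),
                 working_level = attr(x, "working_level"))
}

#' Quantile-quantile data for p-value verification
#'
#' Expected -log10 uniform order statistics versus observed, with a
#' pointwise confidence band from the Beta(k, n + 1 - k) distribution of
#' uniform order statistics. The `deviates` attribute implements the
#' two-plot verification rule: a set of p-values deviates when more than
#' 5% of points fall outside the band; after removing flagged outlier
#' loci a clean second plot confirms the detection.
#'
#' @param p Vector of p-values (at least 10).
#' @param conf Band confidence level.
#' @return A tibble `expected`, `observed`, `lower`, `upper` (all
#'   -log10), with attribute `deviates`.
#' @export
qq_data <- function(p, conf = 0.95) {
  if (length(p) < 10) stop("need at least 10 p-values", call. = FALSE)
  n <- length(p)
  k <- seq_len(n)
  alpha <- (1 - conf) / 2
  out <- tibble::tibble(
    expected = -log10(k / (n + 1)),
    observed = -log10(sort(p)),
    lower = -log10(stats::qbeta(1 - alpha, k, n + 1 - k)),
    upper = -log10(stats::qbeta(alpha, k, n + 1 - k)))
  attr(out, "deviates") <- mean(out$observed < out$lower |
                                  out$observed > out$upper) > 0.05
  class(out) <- c("qq_data", class(out))
  out
}

#' Two-plot QQ verification of an outlier set
#'
#' @param p All p-values; `outlier_loci` logical/index of flagged loci.
#' @param conf Band confidence level.
#' @return A list with `first` and `second` [qq_data()] tables and
#'   `confirmed` (first plot deviates, outlier-removed plot clean).
#' @export
qq_two_step <- function(p, outlier_loci, conf = 0.95) {
  first <- qq_data(p, conf)
  keep <- rep(TRUE, length(p))
  keep[outlier_loci] <- FALSE
  second <- qq_data(p[keep], conf)
  list(first = first, second = second,
       confirmed = attr(first, "deviates") && !attr(second, "deviates"))
}

#' Split a dataset on an outlier report
#'
#' @param G A [geno_matrix()].
#' @param report An `outlier_report` covering every locus of `G` (loci
#'   absent from the report -- e.g. monomorphic loci excluded from the
#'   scan -- are treated as neutral when `unclassified = "neutral"`,
#'   otherwise an error).
#' @param unclassified `"error"` or `"neutral"`.
#' @return A list of [geno_matrix()] objects `neutral`, `directional`,
#'   `balancing`, plus a one-step ledger `ledger`.
#' @export
split_datasets <- function(G, report, unclassified = c("error", "neutral")) {
  unclassified <- match.arg(unclassified)
  cls <- report$class[match(loci(G), report$locus)]
  if (anyNA(cls)) {
    if (unclassified == "error") {
      stop("loci without a class: ",
           paste(utils::head(loci(G)[is.na(cls)], 5), collapse = ", "),
           call. = FALSE)
    }
    cls[is.na(cls)] <- "neutral"
  }
  ledger <- ledger_add(new_filter_ledger(), "outlier_split",
                       ncol(G$scores), sum(cls != "neutral"))
  list(neutral = geno_subset(G, loc = cls == "neutral"),
       directional = geno_subset(G, loc = cls == "directional"),
       balancing = geno_subset(G, loc = cls == "balancing"),
       ledger = ledger)
}

#' Full FST-outlier scan
#'
#' Chains [locus_fst_he()], [simulate_null()] (targeting the observed
#' multilocus theta), [empirical_p()] and [fdr_classify()].
#'
#' @param G A [geno_matrix()].
#' @param map A [pop_map()].
#' @param pops Optional population subset (e.g. the low-divergence basin).
#' @param n_sim_loci Null-cloud size.
#' @param ladder,working_level See [fdr_classify()].
#' @param seed Integer seed.
#' @param fis Inbreeding level for the null genotypes; default matches
#'   HW equilibrium.
#' @return An `outlier_report` (see [fdr_classify()]).
#' @export
outlier_scan <- function(G, map, pops = NULL, n_sim_loci = 50000,
                         ladder = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2),
                         working_level = 0.05, seed = 1L, fis = 0) {
  obs <- locus_fst_he(G, map, pops)
  f <- map_factor(G, map)
  use_pops <- if (is.null(pops)) levels(f) else pops
  sizes <- as.integer(table(f)[use_pops])
  target <- wc_theta(G, map, use_pops)
  if (target <= 0) target <- 1e-3
  null_cloud <- simulate_null(target, length(use_pops), sizes,
                              n_sim_loci = n_sim_loci, seed = seed, fis = fis)
  p <- empirical_p(obs, null_cloud)
  fdr_classify(p, ladder, working_level)
}
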