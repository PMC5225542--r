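# Log mass of the Levene conditional distribution of the heterozygote
# count given the allele counts: P(n_Aa | n, n_A) over genotype
# configurations consistent with the observed allele counts.
levene_log_mass <- function(het, n, n_a) {
  n_b <- 2 * n - n_a
  lgamma(n + 1) - lgamma((n_a - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((n_b - het) / 2 + 1) + het * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
}

hwe_support <- function(n, n_a) {
  n_minor <- min(n_a, 2 * n - n_a)
  seq(n_minor %% 2, n_minor, by = 2)
}

#' Exact test for departure from Hardy-Weinberg equilibrium
#'
#' Exact p-value under Levene's conditional distribution of the
#' heterozygote count given the allele counts: the p-value is the total
#' probability mass of configurations no more probable than the one
#' observed. Full enumeration is used when the minor-allele count is at
#' most `enum_limit`; above that a Guo-Thompson-style Metropolis chain on
#' the heterozygote count is run with the configured number of steps after
#' the dememorisation burn-in.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @param chain_steps,dememorisations Markov-chain length and burn-in used
#'   when enumeration is not exact.
#' @param seed Optional integer seed for the chain.
#' @param method `"auto"` (enumerate when the minor-allele count is small
#'   enough), `"enumeration"` or `"chain"`.
#' @param enum_limit Minor-allele count up to which full enumeration is
#'   used in `"auto"` mode.
#' @return A list with `p_value`, `method`, and the observed configuration.
#'   Monomorphic input returns p = 1 with a warning.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb,
                           chain_steps = 10000, dememorisations = 100000,
                           seed = NULL,
                           method = c("auto", "enumeration", "chain"),
                           enum_limit = 100) {
  method <- match.arg(method)
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) stop("no genotypes", call. = FALSE)
  n_a <- 2 * n_aa + n_ab   # reference allele count
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) {
    warning("monomorphic locus: HWE p-value set to 1")
    return(list(p_value = 1, method = "degenerate", het = n_ab, n = n))
  }
  if (method == "auto") {
    method <- if (min(n_a, n_b) <= enum_limit) "enumeration" else "chain"
  }
  if (method == "enumeration") {
    p <- hwe_enum_p(n, n_a, n_ab)
  } else {
    if (!is.null(seed)) set.seed(seed)
    p <- hwe_chain_p(n, n_a, n_ab, chain_steps, dememorisations)
  }
  list(p_value = p, method = method, het = n_ab, n = n)
}

hwe_enum_p <- function(n, n_a, het_obs) {
  hets <- hwe_support(n, n_a)
  lm <- levene_log_mass(hets, n, n_a)
  m <- exp(lm - max(lm))
  m <- m / sum(m)
  obs <- m[match(het_obs, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts",
                       call. = FALSE)
  sum(m[m <= obs * (1 + 1e-9)])
}

hwe_chain_p <- function(n, n_a, het_obs, chain_steps, dememorisations) {
  n_minor <- min(n_a, 2 * n - n_a)
  lm_obs <- levene_log_mass(het_obs, n, n_a)
  h <- het_obs
  lm_h <- lm_obs
  hits <- 0L
  total <- dememorisations + chain_steps
  u_dir <- stats::runif(total)
  u_acc <- stats::runif(total)
  for (i in seq_len(total)) {
    h_new <- h + if (u_dir[i] < 0.5) 2 else -2
    if (h_new >= n_minor %% 2 && h_new <= n_minor) {
      lm_new <- levene_log_mass(h_new, n, n_a)
      if (log(u_acc[i]) < lm_new - lm_h) {
        h <- h_new
        lm_h <- lm_new
      }
    }
    if (i > dememorisations && lm_h <= lm_obs + 1e-9) hits <- hits + 1L
  }
  hits / chain_steps
}

# Vectorised enumeration across loci for the filter cascade: counts are
# integer vectors. Returns exact Levene p-values (1 for monomorphic loci).
hwe_enum_vec <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  vapply(seq_along(n), function(i) {
    if (n[i] == 0 || n_a[i] == 0 || n_a[i] == 2 * n[i]) return(1)
    hwe_enum_p(n[i], n_a[i], n_ab[i])
  }, numeric(1))
}
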