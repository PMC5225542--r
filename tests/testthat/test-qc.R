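test_that("locus metrics follow the direct counting definitions", {
  G <- make_geno(matrix(c(0, 0, 1, 2, NA), ncol = 1))
  m <- locus_metrics(G)
  expect_equal(m$call_rate, 0.8)
  expect_equal(m$maf, 0.375)        # ref 5 copies, alt 3 of 8
  G2 <- make_geno(matrix(c(0, 1, 2, 2), ncol = 1))  # p = q = 0.5
  expect_equal(locus_metrics(G2)$pic, 0.375)
  # all-missing locus degrades gracefully
  G3 <- make_geno(matrix(NA_integer_, 3, 1))
  m3 <- locus_metrics(G3)
  expect_equal(m3$call_rate, 0)
  expect_true(m3$monomorphic)
})

test_that("repeatability is the concordance over replicate pairs", {
  s <- rbind(a = c(0, 2), a_rep = c(0, 1), b = c(1, 1), b_rep = c(1, 1))
  G <- make_geno(s)
  pairs <- tibble::tibble(id = c("a", "b"), replicate = c("a_rep", "b_rep"))
  m <- locus_metrics(G, pairs)
  expect_equal(m$repeatability, c(1, 0.5))
  # single pair, calls (0,0) and (2,1)
  s1 <- rbind(x = c(0, 2), x_rep = c(0, 1))
  m1 <- locus_metrics(make_geno(s1),
                      tibble::tibble(id = "x", replicate = "x_rep"))
  expect_equal(m1$repeatability, c(1, 0))
})

test_that("clone de-duplication keeps the most informative SNP", {
  # call rates (0.9, 0.7): keep first
  s <- cbind(L1 = c(0, 1, 2, 0, 1, 0, 2, 1, 0, 2),
             L2 = c(0, 1, 2, 0, 1, 0, 2, NA, NA, NA))
  G <- make_geno(s, clone_id = c("c1", "c1"))
  dd <- dedupe_clones(G)
  expect_equal(loci(dd$genotypes), "L1")
  # equal call rates, MAF (low, high): keep second
  s2 <- cbind(L1 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 2),
              L2 = c(0, 1, 2, 0, 1, 0, 2, 1, 0, 2))
  G2 <- make_geno(s2, clone_id = c("c1", "c1"))
  expect_equal(loci(dedupe_clones(G2)$genotypes), "L2")
  expect_error(dedupe_clones(make_geno(s2)), "clone metadata")
})

test_that("de-duplication of a simulated clone-doubled matrix removes half", {
  cfg <- flat_cfg(n_loci = 100, seed = 13L)
  cfg$clone_duplicate_rate <- 0.5
  sim <- simulate_genotypes(cfg)
  dd <- dedupe_clones(sim$genotypes)
  expect_equal(ncol(dd$genotypes$scores), 100L)
  expect_equal(dd$ledger$loci_removed, 50L)
  validate_ledger(dd$ledger)
})

test_that("HWE exact enumeration reproduces the Levene distribution", {
  expect_equal(hwe_exact_test(1, 2, 1)$p_value, 1.0)
  # Levene masses for (2,0,2) are {6/70, 48/70, 16/70}; the observed class
  # (zero heterozygotes) is the least probable, so p = 6/70 (checked against
  # an allele-permutation oracle of the conditional distribution)
  expect_equal(hwe_exact_test(2, 0, 2)$p_value, 6 / 70, tolerance = 1e-12)
  expect_warning(r <- hwe_exact_test(5, 0, 0), "monomorphic")
  expect_equal(r$p_value, 1.0)
})

test_that("the Markov chain agrees with enumeration within Monte-Carlo error", {
  cases <- list(c(18, 4, 8), c(10, 25, 10), c(40, 5, 5), c(3, 7, 20))
  for (cs in cases) {
    p_exact <- hwe_exact_test(cs[1], cs[2], cs[3], method = "enumeration")$p_value
    p_mc <- hwe_exact_test(cs[1], cs[2], cs[3], method = "chain",
                           chain_steps = 10000, dememorisations = 2000,
                           seed = 99L)$p_value
    expect_lt(abs(p_mc - p_exact), 0.02)
  }
})

test_that("a perfectly linked locus pair attains the minimal LD p-value", {
  set.seed(1)
  x <- sample(0:2, 40, replace = TRUE)
  r <- genotypic_ld_test(x, x, n_permutations = 999, seed = 2L)
  expect_equal(r$p_value, 1 / 1000)
})

test_that("LD permutation p-values are null-calibrated for independent loci", {
  set.seed(8)
  ps <- replicate(120, {
    x <- rbinom(60, 2, 0.4)
    y <- rbinom(60, 2, 0.5)
    genotypic_ld_test(dart_from_dosage(x), dart_from_dosage(y),
                      n_permutations = 99)$p_value
  })
  # discrete Monte-Carlo p-values: test uniformity with a chi-square on bins
  bins <- table(cut(ps, breaks = seq(0, 1, 0.25)))
  expect_gt(stats::chisq.test(bins)$p.value, 0.01)
})

test_that("degenerate loci are skipped by the LD test", {
  r <- genotypic_ld_test(rep(0L, 20), rbinom(20, 2, 0.5))
  expect_true(r$skipped)
  expect_true(is.na(r$p_value))
})

test_that("an all-zero threshold cascade is the identity", {
  sim <- simulate_genotypes(flat_cfg(n_loci = 60, seed = 17L))
  th <- qc_thresholds(call_rate_min = 0, pic_min = 0, maf_min = 0,
                      repeatability_min = 0, hwe_alpha = 0, ld_alpha = 0,
                      ld_permutations = 49)
  res <- filter_cascade(sim$genotypes, th, map = sim$map, dedupe = FALSE)
  mono <- sum(locus_metrics(sim$genotypes)$monomorphic)
  expect_equal(sum(res$ledger$loci_removed), mono)  # only monomorphic can go
  expect_equal(ncol(res$genotypes$scores), 60L - mono)
  validate_ledger(res$ledger)
})

test_that("planted low-call-rate loci are removed exactly at the call-rate step", {
  sim <- simulate_genotypes(flat_cfg(n_loci = 100, seed = 19L))
  G <- sim$genotypes
  set.seed(20)
  bad <- sample(100, 40)
  for (l in bad) {
    miss <- sample(nrow(G$scores), round(0.5 * nrow(G$scores)))
    G$scores[miss, l] <- NA_integer_
  }
  th <- qc_thresholds(call_rate_min = 0.65, pic_min = 0, maf_min = 0,
                      repeatability_min = 0, hwe_alpha = 0, ld_alpha = 0,
                      ld_permutations = 49)
  res <- filter_cascade(G, th, map = sim$map, dedupe = FALSE)
  step <- res$ledger[res$ledger$step == "call_rate", ]
  expect_equal(step$loci_removed, 40L)
})

test_that("the cascade ledger is conserved end to end and is seed-deterministic", {
  cfg <- flat_cfg(n_loci = 120, seed = 23L)
  cfg$clone_duplicate_rate <- 0.3
  cfg$missing_rate <- 0.15
  cfg$replicate_fraction <- 0.15
  cfg$genotyping_error_rate <- 0.02
  sim <- simulate_genotypes(cfg)
  th <- qc_thresholds(ld_permutations = 199, ld_alpha = 0.005)
  r1 <- filter_cascade(sim$genotypes, th, sim$replicate_pairs, sim$map, seed = 5L)
  r2 <- filter_cascade(sim$genotypes, th, sim$replicate_pairs, sim$map, seed = 5L)
  validate_ledger(r1$ledger)
  expect_identical(r1$ledger, r2$ledger)
  expect_equal(r1$ledger$loci_out[nrow(r1$ledger)],
               ncol(sim$genotypes$scores) - sum(r1$ledger$loci_removed))
  expect_identical(r1$genotypes$scores, r2$genotypes$scores)
})
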