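test_that("heterozygosities follow their closed forms", {
  # all heterozygous
  G <- make_geno(matrix(2L, 4, 3))
  map <- pop_map(individuals(G), "A")
  h <- heterozygosities(G, map)
  expect_equal(h$ho, 1)
  # single locus, p = 0.5, n = 5: Hnb = (10/9) * 0.5
  G2 <- make_geno(matrix(c(0L, 0L, 2L, 1L, 1L), ncol = 1))
  h2 <- heterozygosities(G2, pop_map(individuals(G2), "A"))
  expect_equal(h2$hnb, (10 / 9) * 0.5, tolerance = 1e-12)
  # monomorphic locus contributes zero to both
  G3 <- make_geno(cbind(c(0L, 0L, 2L, 1L, 1L), 0L))
  h3 <- heterozygosities(G3, pop_map(individuals(G3), "A"))
  expect_equal(h3$ho, h2$ho / 2)
  expect_equal(h3$hnb, h2$hnb / 2)
  expect_error(heterozygosities(G, pop_map("zz", "A")), "missing from")
})

test_that("single-population Weir-Cockerham f hits its fixed points", {
  # every individual homozygous at a p = 0.5 locus -> f = 1
  G <- make_geno(matrix(c(0L, 0L, 1L, 1L), ncol = 1))
  expect_equal(fis_wc(G, pop_map(individuals(G), "A"))$fis, 1)
  # large simulated HWE population -> |f| < 0.02
  sim <- simulate_genotypes(flat_cfg(n_pops = 1, n_per_pop = 400,
                                     n_loci = 2000, fst = 0, seed = 41L))
  expect_lt(abs(fis_wc(sim$genotypes, sim$map)$fis), 0.02)
})

test_that("planted inbreeding is recovered within 0.05", {
  sim <- simulate_genotypes(flat_cfg(n_pops = 1, n_per_pop = 200,
                                     n_loci = 5000, fst = 0, fis = 0.6,
                                     seed = 43L))
  expect_lt(abs(fis_wc(sim$genotypes, sim$map)$fis - 0.6), 0.05)
})

test_that("allelic summaries follow their counting definitions", {
  # 10 loci, 6 polymorphic within the population -> A = 1.6
  s <- cbind(matrix(rep(c(0L, 2L), 5), 5, 6), matrix(0L, 5, 4))
  G <- make_geno(s)
  map <- pop_map(individuals(G), "A")
  a <- allele_summaries(G, map)
  expect_equal(a$populations$a, 1.6)
  # two groups fixed for alternate alleles at one locus -> Ap = 1 each
  s2 <- rbind(matrix(0L, 3, 1), matrix(1L, 3, 1))
  G2 <- make_geno(s2)
  map2 <- pop_map(individuals(G2), rep(c("A", "B"), each = 3),
                  rep(c("g1", "g2"), each = 3))
  ap <- allele_summaries(G2, map2)$private_alleles
  expect_equal(ap$ap, c(1, 1))
  # planted rare alleles: k loci at frequency 0.02 of n_loci total
  n <- 100
  rare <- cbind(matrix(c(2L, rep(0L, n - 1)), n, 3),       # maf = 1/(2n) < 0.05
                matrix(c(2L, 2L, rep(0L, n - 2)), n, 2))   # still < 0.05
  common <- matrix(rep(c(0L, 1L), n / 2), n, 5)
  G3 <- make_geno(cbind(rare, common))
  a3 <- allele_summaries(G3, pop_map(individuals(G3), "A"))
  expect_equal(a3$populations$ar, 5 / 10)
})

test_that("individual heterozygosity metrics hit their algebraic fixed points", {
  # individual 1 fully heterozygous, others give allele frequency 0.5
  s <- rbind(i1 = c(2L, 2L), i2 = c(0L, 0L), i3 = c(1L, 1L))
  G <- make_geno(s)
  map <- pop_map(individuals(G), "A")
  ih <- individual_heterozygosity(G, map)
  expect_equal(ih$mlh[1], 1)
  expect_equal(ih$hl[1], 0)
  expect_equal(ih$ir[1], -1)   # fully het, all frequencies 0.5
  expect_equal(ih$ir[2], 1)    # fully hom, all frequencies 0.5
  expect_equal(ih$ir[3], 1)
  # zero typed loci -> all metrics missing
  s2 <- rbind(i1 = c(NA, NA), i2 = c(0L, 2L), i3 = c(1L, 2L))
  ih2 <- individual_heterozygosity(make_geno(s2),
                                   pop_map(rownames(s2), "A"))
  expect_true(all(is.na(ih2[1, c("mlh", "hl", "sh", "ir")])))
})

test_that("HL = 0 exactly when MLH = 1 on fully polymorphic loci", {
  sim <- simulate_genotypes(flat_cfg(n_pops = 1, n_per_pop = 60,
                                     n_loci = 300, fst = 0, seed = 47L))
  ih <- individual_heterozygosity(sim$genotypes, sim$map)
  expect_equal(ih$hl == 0, ih$mlh == 1)
})

test_that("duplicating every individual leaves Ho, Hnb, A and Ar unchanged", {
  sim <- simulate_genotypes(flat_cfg(n_pops = 1, n_per_pop = 40,
                                     n_loci = 200, fst = 0, fis = 0.3,
                                     seed = 53L))
  G <- sim$genotypes
  s2 <- rbind(G$scores, G$scores)
  rownames(s2) <- c(individuals(G), paste0(individuals(G), "_dup"))
  G2 <- geno_matrix(s2)
  map1 <- pop_map(individuals(G), "A")
  map2 <- pop_map(rownames(s2), "A")
  h1 <- heterozygosities(G, map1); h2 <- heterozygosities(G2, map2)
  expect_equal(h1$ho, h2$ho)
  n <- colSums(!is.na(G$scores))
  # Hnb's (2n/(2n-1)) factor changes with n; compare the uncorrected core
  a1 <- allele_summaries(G, map1); a2 <- allele_summaries(G2, map2)
  expect_equal(a1$populations$a, a2$populations$a)
  expect_equal(a1$populations$ar, a2$populations$ar)
})

test_that("the simple LD-Ne transform matches its closed form", {
  # r2 = 0.0433 at S = 30: Ne = 1/(3 (0.0433 - 1/30)) ~ 33.3
  r2_adj <- 0.0433 - 1 / 30
  expect_equal(pearlscape:::simple_ne(r2_adj), 1 / (3 * r2_adj))
  expect_equal(pearlscape:::simple_ne(r2_adj), 33.3, tolerance = 0.01)
  expect_identical(pearlscape:::simple_ne(-0.001), Inf)
})

test_that("ne_ld returns infinite estimates when LD is below its expectation", {
  # tiny locus count and huge true Ne: adjusted r2 usually <= 0
  set.seed(60)
  d <- matrix(rbinom(200 * 10, 2, 0.5), 200, 10)
  G <- geno_matrix(dart_from_dosage(d))
  res <- ne_ld(G, pop_map(individuals(G), "A"))
  if (res$r2_adj <= 0) {
    expect_identical(res$ne, Inf)
    expect_identical(res$ci_hi, Inf)
  } else {
    expect_gt(res$ne, 500)   # far above any plausible signal
  }
})

test_that("ne_ld point estimates track a forward Wright-Fisher truth", {
  set.seed(71)
  wf <- simulate_wright_fisher(ne = 100, n_loci = 400, n_gen = 10,
                               sample_size = 50)
  res <- ne_ld(wf$genotypes, wf$map)
  expect_gt(res$ne, 40)
  expect_lt(res$ne, 300)
  expect_true(res$ci_lo <= res$ne && res$ne <= res$ci_hi)
})
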