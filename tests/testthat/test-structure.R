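test_that("pairwise theta is maximal for fixed alternate homozygotes", {
  s <- rbind(matrix(0L, 10, 20), matrix(1L, 10, 20))
  G <- make_geno(s)
  map <- two_pop_map(G, 10)
  res <- pairwise_fst(G, map, n_perm = 99, seed = 1L)
  expect_equal(res$values["A", "B"], 1)
  expect_lt(res$p_values["A", "B"], 0.05)
})

test_that("two samples from one gene pool give theta near zero and a large p", {
  sim <- simulate_genotypes(flat_cfg(n_pops = 2, n_per_pop = 60,
                                     n_loci = 800, fst = 0, seed = 61L))
  res <- pairwise_fst(sim$genotypes, sim$map, n_perm = 199, seed = 2L)
  expect_lt(abs(res$values[1, 2]), 0.01)
  expect_gt(res$p_values[1, 2], 0.01)
})

test_that("pairwise theta recovers a planted two-population FST", {
  sim <- simulate_genotypes(flat_cfg(n_pops = 2, n_per_pop = 100,
                                     n_loci = 2000, fst = 0.10, seed = 67L))
  res <- pairwise_fst(sim$genotypes, sim$map, n_perm = 0)
  expect_gt(res$values[1, 2], 0.08)
  expect_lt(res$values[1, 2], 0.12)
})

test_that("theta and DS are invariant to relabelling individuals within pops", {
  sim <- simulate_genotypes(flat_cfg(n_pops = 2, n_per_pop = 30,
                                     n_loci = 300, fst = 0.05, seed = 71L))
  G <- sim$genotypes; map <- sim$map
  set.seed(4)
  perm <- unlist(lapply(unique(map$population), function(p)
    sample(which(map$population == p))))
  G2 <- geno_matrix(G$scores[perm, ], G$loci)
  expect_equal(pairwise_fst(G, map, 0)$values,
               pairwise_fst(G2, map, 0)$values)
  expect_equal(nei_ds(G, map)$values, nei_ds(G2, map)$values)
})

test_that("Nei DS matches its infinite-sample limit and is symmetric", {
  # pop A fixed alternate (p = 1), pop B at p = 0.5: DS -> -ln(0.5/sqrt(0.5))
  s <- rbind(matrix(1L, 500, 1),
             matrix(rep(c(0L, 1L), 250), ncol = 1))
  G <- make_geno(s)
  map <- two_pop_map(G, 500)
  ds <- nei_ds(G, map)
  expect_equal(ds$values["A", "B"], -log(0.5 / sqrt(0.5)), tolerance = 0.01)
  expect_equal(ds$values["A", "B"], ds$values["B", "A"])
  # identical frequencies, large n -> DS ~ 0
  sim <- simulate_genotypes(flat_cfg(n_pops = 2, n_per_pop = 150,
                                     n_loci = 1000, fst = 0, seed = 73L))
  expect_lt(abs(nei_ds(sim$genotypes, sim$map)$values[1, 2]), 0.005)
})

test_that("AMOVA percentages sum to 100 and vanish under panmixia", {
  cfg <- genotype_sim_config(n_regions = 2, pops_per_region = c(2, 2),
                             n_per_pop = 40, n_loci = 400,
                             fst_between_regions = 0, fst_within_region = 0,
                             fis = 0, missing_rate = 0.05,
                             clone_duplicate_rate = 0,
                             n_directional_outliers = 0,
                             n_balancing_outliers = 0, replicate_fraction = 0,
                             genotyping_error_rate = 0, seed = 79L)
  sim <- simulate_genotypes(cfg)
  am <- hierarchical_amova(sim$genotypes, sim$map, n_perm = 0)
  expect_equal(sum(am$table$percent), 100, tolerance = 1e-8)
  expect_lt(abs(am$table$percent[1]), 2)
  expect_lt(abs(am$table$percent[2]), 2)
})

test_that("AMOVA recovers a planted between-region component", {
  cfg <- genotype_sim_config(n_regions = 2, pops_per_region = c(3, 3),
                             n_per_pop = 30, n_loci = 800,
                             fst_between_regions = 0.18,
                             fst_within_region = 0.01, fis = 0,
                             missing_rate = 0, clone_duplicate_rate = 0,
                             n_directional_outliers = 0,
                             n_balancing_outliers = 0, replicate_fraction = 0,
                             genotyping_error_rate = 0, seed = 83L)
  sim <- simulate_genotypes(cfg)
  am <- hierarchical_amova(sim$genotypes, sim$map, n_perm = 49, seed = 3L)
  expect_gt(am$table$percent[1], 13)
  expect_lt(am$table$percent[1], 23)
  expect_lt(am$p_values$p_value[1], 0.25)   # strong signal, limited perms
})

test_that("AMOVA permutation p-values are calibrated under the null", {
  set.seed(11)
  ps <- replicate(30, {
    d <- matrix(rbinom(60 * 60, 2, 0.5), 60, 60)
    G <- geno_matrix(dart_from_dosage(d))
    map <- pop_map(individuals(G), rep(c("A", "B", "C", "D"), each = 15),
                   rep(c("r1", "r2"), each = 30))
    hierarchical_amova(G, map, n_perm = 19,
                       seed = sample.int(1e6, 1))$p_values$p_value[1]
  })
  # null p-values should not pile up near 0
  expect_gt(mean(ps > 0.2), 0.5)
})

test_that("Mantel r is exact for affinely related matrices", {
  set.seed(5)
  m1 <- as.matrix(dist(matrix(rnorm(12), 6)))
  r <- mantel_test(m1, 3 * m1, n_perm = 99)
  expect_equal(r$r, 1)
  expect_equal(r$r_squared, 1)
  expect_error(mantel_test(m1, matrix(1, 6, 6) - diag(6) * 0), "constant")
})

test_that("Monte-Carlo Mantel p is within 1/25 of the exhaustive p on 4x4", {
  set.seed(6)
  for (k in 1:3) {
    m1 <- as.matrix(dist(matrix(rnorm(8), 4)))
    m2 <- as.matrix(dist(matrix(rnorm(8), 4)))
    exact <- mantel_test(m1, m2, exhaustive = TRUE)
    mc <- mantel_test(m1, m2, n_perm = 999, seed = k)
    expect_lt(abs(mc$p_value - exact$p_value), 1 / 25)
  }
})

test_that("Mantel agrees with an independent implementation", {
  set.seed(7)
  m1 <- as.matrix(dist(matrix(rnorm(20), 10)))
  m2 <- as.matrix(dist(matrix(rnorm(20), 10)))
  ours <- mantel_test(m1, m2, n_perm = 999, seed = 8)
  ref <- vegan::mantel(m1, m2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
})

test_that("great-circle distances match the sphere geometry", {
  expect_equal(great_circle_km(c(10, 20), c(10, 20)), 0)
  expect_equal(great_circle_km(c(0, 0), c(0, 90)), 2 * pi * 6371 / 4,
               tolerance = 1e-6)
  expect_equal(great_circle_km(c(0, 0), c(0, 180)), 2 * pi * 6371 / 2,
               tolerance = 1e-6)
})

test_that("shared-allele distance hits its genotype fixed points", {
  s <- rbind(i1 = c(0L, 2L, 1L), i2 = c(0L, 2L, 1L))
  expect_equal(max(abs(one_minus_psa(make_geno(s)))), 0)
  s2 <- rbind(i1 = c(0L, 0L), i2 = c(1L, 1L))
  expect_equal(one_minus_psa(make_geno(s2))["i1", "i2"], 1)
  s3 <- rbind(i1 = matrix(2L, 1, 1), i2 = matrix(0L, 1, 1))
  expect_equal(one_minus_psa(make_geno(s3))["i1", "i2"], 0.5)
  s4 <- rbind(i1 = c(0L, NA), i2 = c(NA, 1L))
  expect_warning(d4 <- one_minus_psa(make_geno(s4)), "no shared")
  expect_true(is.na(d4["i1", "i2"]))
})

test_that("mutual kNN graphs satisfy the mutuality contract", {
  x <- matrix(c(1:10, 101:110), ncol = 1)   # two well-separated clusters
  D <- as.matrix(dist(x))
  rownames(D) <- colnames(D) <- paste0("i", 1:20)
  g <- mutual_knn_network(D, k = 5)
  expect_equal(attr(g, "n_components"), 2)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  knn <- matrix(FALSE, 20, 20)
  for (i in 1:20) {
    nb <- order(D[i, -i])[1:5]
    knn[i, seq_len(20)[-i][nb]] <- TRUE
  }
  expect_equal(adj > 0, knn & t(knn), ignore_attr = TRUE)
  g_all <- mutual_knn_network(D, k = 19)
  expect_equal(attr(g_all, "n_components"), 1)
  expect_equal(igraph::gsize(g_all), choose(20, 2))
})

test_that("neighbour joining recovers additive trees exactly", {
  # 3 taxa: closed-form branch lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(t3))[c("a", "b", "c"), c("a", "b", "c")]),
               unname(D3), tolerance = 1e-9)
  # additive 4-taxon matrix from a known tree
  tr <- ape::read.tree(text = "((a:1,b:2):1.5,(c:0.5,d:3):0.5);")
  D4 <- as.matrix(ape::cophenetic.phylo(tr))
  t4 <- nj_tree(D4)
  expect_equal(as.matrix(ape::cophenetic.phylo(t4))[rownames(D4), colnames(D4)],
               D4, tolerance = 1e-9)
  # same unrooted topology as the reference implementation
  ref <- ape::nj(D4)
  expect_equal(ape::dist.topo(ape::unroot(t4), ape::unroot(ref))[1], 0)
  expect_error(nj_tree(D4[1:2, 1:2]), "at least 3")
})

test_that("negative NJ branch lengths are clamped with the deficit transferred", {
  D <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.001   # force a near-degenerate join
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("directional migration is symmetric for exchangeable populations", {
  sim <- simulate_genotypes(flat_cfg(n_pops = 2, n_per_pop = 80,
                                     n_loci = 1000, fst = 0.03, seed = 91L))
  mig <- directional_migration(sim$genotypes, sim$map)
  expect_equal(max(mig$m, na.rm = TRUE), 1)
  expect_lt(abs(mig$m[1, 2] - mig$m[2, 1]), 0.1)
})

test_that("a recently founded population shows stronger inflow from its source", {
  set.seed(13)
  hits <- 0
  for (k in 1:10) {
    p_anc <- runif(600, 0.1, 0.9)
    pa <- pearl_bn(p_anc, 0.05); pb <- pearl_bn(p_anc, 0.05)
    pc <- pmin(pmax(pa + rnorm(600, 0, 0.02), 0), 1)  # C founded from A
    d <- rbind(sim_pop(40, pa), sim_pop(40, pb), sim_pop(40, pc))
    G <- geno_matrix(dart_from_dosage(d))
    map <- pop_map(individuals(G), rep(c("A", "B", "C"), each = 40))
    mig <- directional_migration(G, map)
    if (mig$m["A", "C"] > mig$m["B", "C"]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the printed pairwise table round-trips through the reader", {
  path <- system.file("extdata", "pairwise_fst_ds.csv", package = "pearlscape")
  tabs <- read_pairwise_table(path)
  expect_true(isSymmetric(tabs$fst$values))
  expect_true(isSymmetric(tabs$ds$values))
  expect_equal(tabs$fst$values["abrolhos", "gbr"], 0.1311)
  expect_equal(tabs$ds$values["gbr", "abrolhos"], 0.056)
})
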