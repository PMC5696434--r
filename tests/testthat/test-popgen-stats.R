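test_that("theta equals the literal Weir-Cockerham transcription", {
  for (seed in 1:6) {
    set.seed(seed)
    freqs <- lapply(sample(2:5, 3, replace = TRUE), function(k) {
      f <- rgamma(k, 1); f / sum(f)
    })
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    g <- random_two_pop_genotypes(n1, n2, freqs)
    ref <- wc_theta_transcription(
      g$a1[1:n1, , drop = FALSE], g$a2[1:n1, , drop = FALSE],
      g$a1[-(1:n1), , drop = FALSE], g$a2[-(1:n1), , drop = FALSE])
    expect_equal(as.numeric(fst_weir_cockerham(g)), ref, tolerance = 1e-12)
  }
})

test_that("theta is 1 for populations fixed for different alleles", {
  g <- genotype_matrix(
    a1 = rbind(matrix(1L, 10, 3), matrix(2L, 10, 3)),
    a2 = rbind(matrix(1L, 10, 3), matrix(2L, 10, 3)),
    pop = rep(c("a", "b"), each = 10))
  expect_equal(as.numeric(fst_weir_cockerham(g)), 1)
})

test_that("theta is centred on zero for samples from one population", {
  set.seed(21)
  freqs <- unclass(founder_profile())[1:4]
  draws <- replicate(200, as.numeric(
    fst_weir_cockerham(random_two_pop_genotypes(50, 50, freqs))))
  expect_lt(abs(mean(draws)), 3 * sd(draws) / sqrt(length(draws)))
})

test_that("theta is invariant to allele relabeling and locus order", {
  set.seed(22)
  freqs <- list(c(0.5, 0.3, 0.2), c(0.7, 0.3))
  g <- random_two_pop_genotypes(15, 15, freqs,
                                freqs2 = list(c(0.2, 0.3, 0.5), c(0.4, 0.6)))
  base <- as.numeric(fst_weir_cockerham(g))
  # relabel alleles at locus 1 with an arbitrary injective map
  map <- c(7L, 3L, 9L)
  g2 <- g
  g2$a1[, 1] <- map[g$a1[, 1]]; g2$a2[, 1] <- map[g$a2[, 1]]
  expect_equal(as.numeric(fst_weir_cockerham(g2)), base, tolerance = 1e-12)
  # permute loci
  g3 <- genotype_matrix(g$a1[, 2:1], g$a2[, 2:1], g$pop, g$loci[2:1])
  expect_equal(as.numeric(fst_weir_cockerham(g3)), base, tolerance = 1e-12)
})

test_that("theta on all-monomorphic data is signalled, never silently zero", {
  g <- genotype_matrix(matrix(1L, 8, 2), matrix(1L, 8, 2),
                       rep(c("a", "b"), each = 4))
  expect_warning(out <- fst_weir_cockerham(g), "not estimable")
  expect_true(is.na(out))
})

test_that("individuals missing a locus are dropped from that locus only", {
  set.seed(23)
  freqs <- list(c(0.6, 0.4), c(0.5, 0.3, 0.2))
  g <- random_two_pop_genotypes(10, 10, freqs)
  g$a1[1, 2] <- NA_integer_; g$a2[1, 2] <- NA_integer_
  # oracle: locus 1 on everyone + locus 2 with individual 1 removed
  part1 <- list(a1 = g$a1[, 1, drop = FALSE], a2 = g$a2[, 1, drop = FALSE])
  keep <- 2:20
  ref <- local({
    r1 <- wc_theta_transcription(part1$a1[1:10, , drop = FALSE],
                                 part1$a2[1:10, , drop = FALSE],
                                 part1$a1[11:20, , drop = FALSE],
                                 part1$a2[11:20, , drop = FALSE])
    # recompute the component sums by pooling both loci manually
    g_l1 <- genotype_matrix(g$a1[, 1, drop = FALSE], g$a2[, 1, drop = FALSE],
                            g$pop)
    g_l2 <- genotype_matrix(g$a1[keep, 2, drop = FALSE],
                            g$a2[keep, 2, drop = FALSE], g$pop[keep])
    list(l1 = g_l1, l2 = g_l2)
  })
  per_locus <- attr(fst_weir_cockerham(g), "per_locus")
  expect_equal(per_locus[[1]],
               as.numeric(fst_weir_cockerham(ref$l1)), tolerance = 1e-12)
  expect_equal(per_locus[[2]],
               as.numeric(fst_weir_cockerham(ref$l2)), tolerance = 1e-12)
})

test_that("DAPC separates fixed-difference populations perfectly", {
  g <- genotype_matrix(
    a1 = rbind(matrix(1L, 20, 4), matrix(2L, 20, 4)),
    a2 = rbind(matrix(1L, 20, 4), matrix(2L, 20, 4)),
    pop = rep(c("source", "isolated"), each = 20))
  expect_equal(as.numeric(dapc_misassignment(g)), 0)
})

test_that("DAPC misassignment is a proportion, symmetric under focal swap", {
  set.seed(24)
  freqs <- unclass(founder_profile())[1:4]
  vals_a <- vals_b <- numeric(30)
  for (i in 1:30) {
    g <- random_two_pop_genotypes(25, 25, freqs)
    vals_a[i] <- dapc_misassignment(g, focal = "isolated")
    vals_b[i] <- dapc_misassignment(g, focal = "source")
  }
  expect_true(all(vals_a >= 0 & vals_a <= 1))
  # exchangeable samples: the two focal choices have the same distribution
  se <- sqrt((var(vals_a) + var(vals_b)) / 30)
  expect_lt(abs(mean(vals_a) - mean(vals_b)), 3 * se)
})

test_that("DAPC misassignment decreases as divergence grows", {
  set.seed(25)
  null_freqs <- list(c(0.5, 0.5), c(0.5, 0.3, 0.2), c(0.6, 0.4))
  div_freqs <- list(c(0.9, 0.1), c(0.1, 0.2, 0.7), c(0.15, 0.85))
  m_null <- mean(replicate(15, dapc_misassignment(
    random_two_pop_genotypes(30, 30, null_freqs))))
  m_div <- mean(replicate(15, dapc_misassignment(
    random_two_pop_genotypes(30, 30, null_freqs, div_freqs))))
  expect_gt(m_null, m_div)
})

test_that("DAPC honours the retention policy and rejects degenerate input", {
  set.seed(26)
  g <- random_two_pop_genotypes(20, 20, unclass(founder_profile())[1:4])
  out <- dapc_misassignment(g)
  expect_lte(attr(out, "n_pcs"), floor(40 / 3))
  out2 <- dapc_misassignment(g, n_pcs = 2)
  expect_identical(attr(out2, "n_pcs"), 2L)
  gd <- genotype_matrix(matrix(1L, 10, 2), matrix(1L, 10, 2),
                        rep(c("a", "b"), each = 5))
  expect_error(dapc_misassignment(gd), "degenerate")
})

test_that("the K=1 sampler is deterministic up to Monte-Carlo noise", {
  set.seed(27)
  g <- random_two_pop_genotypes(20, 20, unclass(founder_profile())[1:4])
  lnpds <- replicate(5, admixture_loglik_sampler(g, 1, mcmc = 2000,
                                                 burnin = 2000)$lnpd)
  expect_lt(diff(range(lnpds)), 2)
})

test_that("admixture proportions are proper and LnP(D) ranks a separable case", {
  set.seed(28)
  g <- genotype_matrix(
    a1 = rbind(matrix(1L, 15, 4), matrix(2L, 15, 4)),
    a2 = rbind(matrix(1L, 15, 4), matrix(2L, 15, 4)),
    pop = rep(c("source", "isolated"), each = 15))
  f1 <- admixture_loglik_sampler(g, 1, mcmc = 2000, burnin = 2000)
  f2 <- admixture_loglik_sampler(g, 2, mcmc = 2000, burnin = 2000)
  expect_gt(f2$lnpd, f1$lnpd)
  expect_equal(rowSums(f2$q), rep(1, 30), tolerance = 1e-9)
  # with full divergence z never leaves the home cluster, so the posterior
  # mean of the top admixture component is (1 + 2L)/(2 + 2L) with L = 4 loci
  purity <- apply(f2$q, 1, max)
  expect_equal(mean(purity), 9 / 10, tolerance = 0.02)
})

test_that("LnP(D) is invariant to label switching across independent runs", {
  set.seed(29)
  g <- genotype_matrix(
    a1 = rbind(matrix(1L, 15, 4), matrix(2L, 15, 4)),
    a2 = rbind(matrix(1L, 15, 4), matrix(2L, 15, 4)),
    pop = rep(c("source", "isolated"), each = 15))
  runs <- replicate(4, admixture_loglik_sampler(g, 2, mcmc = 3000,
                                                burnin = 3000)$lnpd)
  # different random initialisations permute cluster labels freely, but the
  # likelihood-based LnP(D) must agree up to Monte-Carlo error
  expect_lt(diff(range(runs)), 3)
})

test_that("best_k recovers K = 2 for a separable two-population sample", {
  set.seed(30)
  g <- genotype_matrix(
    a1 = rbind(matrix(1L, 15, 4), matrix(2L, 15, 4)),
    a2 = rbind(matrix(1L, 15, 4), matrix(2L, 15, 4)),
    pop = rep(c("source", "isolated"), each = 15))
  k <- best_k(g, k_max = 3, runs = 2, mcmc = 2000, burnin = 2000)
  expect_identical(as.integer(k), 2L)
  expect_length(attr(k, "mean_lnpk"), 3L)
})

test_that("mean expected heterozygosity averages loci, fixed loci as zero", {
  p <- quick_params()
  set.seed(31)
  pop <- init_population(allele_freqs(list(a = 1, b = 1)), 20, p)
  expect_equal(mean_expected_heterozygosity(pop), 0)
  # a deterministic half-and-half biallelic population
  pop2 <- init_population(allele_freqs(list(c(0.5, 0.5))), 10, p)
  pop2$a1[, 1] <- 1L; pop2$a2[, 1] <- 2L
  expect_equal(mean_expected_heterozygosity(pop2), 0.5)
})

test_that("a freshly founded population shows the founder He profile", {
  set.seed(32)
  p <- sim_params()
  pop <- init_population(founder_profile(), 1000, p)
  target <- mean(expected_heterozygosity(founder_profile()))
  # sampling noise of mean He at n = 1000 is well under 0.01
  expect_lt(abs(mean_expected_heterozygosity(pop) - target), 0.015)
})
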