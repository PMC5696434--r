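test_that("founding draws Hardy-Weinberg genotypes from the frequencies", {
  set.seed(101)
  af <- allele_freqs(list(bi = c(0.5, 0.5), fixed = 1))
  p <- quick_params(n_source = 10000L)
  pop <- init_population(af, 10000, p)
  # observed heterozygosity at the 50/50 locus: binomial oracle, 3-sigma band
  het <- mean(pop$a1[, 1] != pop$a2[, 1])
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000))
  # a fixed locus founds every individual homozygous
  expect_true(all(pop$a1[, 2] == 1L & pop$a2[, 2] == 1L))
})

test_that("initial ages follow the truncated-geometric stationary distribution", {
  set.seed(102)
  p <- quick_params(annual_survival = 0.96, max_age = 62L)
  pop <- init_population(founder_profile(), 20000, p)
  mu <- truncated_geometric_mean(0.96, 62)
  a <- 0:62
  w <- 0.96^a / sum(0.96^a)
  sd_age <- sqrt(sum(a^2 * w) - mu^2)
  expect_lt(abs(mean(pop$age) - mu), 3 * sd_age / sqrt(20000))
  expect_true(all(pop$age >= 0 & pop$age <= 62))
})

test_that("with certain survival a year only increments ages", {
  set.seed(103)
  p <- quick_params(annual_survival = 1, max_age = 10000L)
  pop <- init_population(founder_profile(), 40, p)
  nxt <- advance_year(pop, p)
  expect_identical(nxt$a1, pop$a1)
  expect_identical(nxt$a2, pop$a2)
  expect_identical(nxt$age, pop$age + 1L)
})

test_that("annual death counts match the binomial oracle", {
  set.seed(104)
  p <- sim_params(n_source = 1000L, annual_survival = 0.96,
                  max_age = 1000000L, horizon = 0L)
  pop <- init_population(founder_profile(), 1000, p)
  pop$age <- rep(0L, 1000)  # keep the age cap out of reach
  trials <- 2000
  deaths <- replicate(trials, sum(advance_year(pop, p)$age == 0L))
  expect_lt(abs(mean(deaths) - 1000 * 0.04),
            3 * sqrt(1000 * 0.04 * 0.96) / sqrt(trials))
})

test_that("the maximum-age cap is exact", {
  set.seed(105)
  p <- quick_params(max_age = 2L)
  pop <- init_population(founder_profile(), 50, p)
  for (y in 1:10) {
    pop <- advance_year(pop, p)
    expect_true(all(pop$age <= 2L))
  }
})

test_that("census size is constant and alleles are only ever lost", {
  set.seed(106)
  af <- freqs_matching_he(c(0.6, 0.75, 0.3), n_alleles = c(4, 6, 3))
  p <- quick_params(n_source = 30L, max_age = 3L)
  pop <- init_population(af, 30, p)
  seen <- lapply(seq_len(3), function(l) unique(c(pop$a1[, l], pop$a2[, l])))
  fixed_at <- rep(NA_integer_, 3)
  for (y in 1:60) {
    pop <- advance_year(pop, p)
    expect_identical(pop_size(pop), 30L)
    for (l in 1:3) {
      now <- unique(c(pop$a1[, l], pop$a2[, l]))
      # no novel alleles ever appear (no mutation)
      expect_true(all(now %in% seen[[l]]))
      seen[[l]] <- now
      if (is.na(fixed_at[l]) && length(now) == 1L) fixed_at[l] <- now
      # fixation is absorbing
      if (!is.na(fixed_at[l]))
        expect_true(all(c(pop$a1[, l], pop$a2[, l]) == fixed_at[l]))
    }
  }
})

test_that("one year of full turnover reproduces Wright-Fisher drift variance", {
  set.seed(107)
  af <- allele_freqs(list(c(0.5, 0.5)))
  N <- 50
  p <- sim_params(n_source = N, n_isolated = N, annual_survival = 1e-9,
                  max_age = 1L, subsample_size = N, horizon = 0L)
  reps <- 1500
  phat <- replicate(reps, {
    pop <- init_population(af, N, p)
    # measure the change over one generation from the realized frequency
    p0 <- mean(c(pop$a1[, 1], pop$a2[, 1]) == 1L)
    pop <- advance_year(pop, p)
    mean(c(pop$a1[, 1], pop$a2[, 1]) == 1L) - p0
  })
  v_expect <- 0.5 * 0.5 / (2 * N)
  mc_band <- 3 * v_expect * sqrt(2 / (reps - 1))
  expect_lt(abs(var(phat) - v_expect), mc_band + v_expect / (2 * N))
})

test_that("the split copies founders without disturbing the source", {
  set.seed(108)
  p <- quick_params()
  src <- init_population(founder_profile(), 60, p)
  src_before <- src
  iso <- split_isolated(src, 60)
  expect_identical(src, src_before)
  # full-size split carries identical allele counts
  for (l in seq_len(ncol(src$a1)))
    expect_identical(sort(c(iso$a1[, l], iso$a2[, l])),
                     sort(c(src$a1[, l], src$a2[, l])))
  expect_error(split_isolated(src, 61), "exceeds")
  set.seed(42); s1 <- split_isolated(src, 10)
  set.seed(42); s2 <- split_isolated(src, 10)
  expect_identical(s1, s2)
})

test_that("replicates are fully reproducible from their seed", {
  p <- quick_params()
  an <- analysis_config(stat_years = c(0, 5, 10), do_clustering = FALSE)
  t1 <- run_replicate(p, founder_profile(), seed = 99, analysis = an)
  t2 <- run_replicate(p, founder_profile(), seed = 99, analysis = an)
  expect_identical(t1, t2)
  t3 <- run_replicate(p, founder_profile(), seed = 100, analysis = an)
  expect_false(identical(t1$yearly, t3$yearly))
})

test_that("a zero-horizon replicate records only the split-time state", {
  p <- quick_params(horizon = 0L, n_source = 100L, n_isolated = 50L,
                    subsample_size = 40L)
  tr <- run_replicate(p, founder_profile(), seed = 5,
                      analysis = analysis_config(do_clustering = FALSE))
  expect_identical(nrow(tr$yearly), 1L)
  expect_identical(tr$yearly$year, 0L)
  # two samples of one just-split population: theta is sampling noise only
  expect_lt(abs(tr$yearly$theta), 0.05)
})

test_that("advancing an empty or pair-less population fails loudly", {
  p <- quick_params()
  pop <- init_population(founder_profile(), 1, p)
  pop$age <- 1000L  # force a certain death with no possible parent pair
  expect_error(advance_year(pop, quick_params(max_age = 2L)),
               "fewer than two adults")
})
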