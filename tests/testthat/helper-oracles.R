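# Independent oracles used by the unit and acceptance tests.

# Literal scalar transcription of the Weir & Cockerham (1984) variance
# components a, b, c, kept deliberately separate from the package's
# vectorised implementation.  Two populations, any number of alleles,
# complete data.
wc_theta_transcription <- function(pop1_a1, pop1_a2, pop2_a1, pop2_a2) {
  stopifnot(ncol(pop1_a1) == ncol(pop2_a1))
  r <- 2
  sum_a <- 0
  sum_abc <- 0
  for (l in seq_len(ncol(pop1_a1))) {
    x1 <- cbind(pop1_a1[, l], pop1_a2[, l])
    x2 <- cbind(pop2_a1[, l], pop2_a2[, l])
    alleles <- sort(unique(c(x1, x2)))
    if (length(alleles) < 2) next
    n1 <- nrow(x1)
    n2 <- nrow(x2)
    n_bar <- (n1 + n2) / r
    n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
    for (allele in alleles) {
      p1 <- sum(x1 == allele) / (2 * n1)
      p2 <- sum(x2 == allele) / (2 * n2)
      h1 <- sum((x1[, 1] == allele) != (x1[, 2] == allele)) / n1
      h2 <- sum((x2[, 1] == allele) != (x2[, 2] == allele)) / n2
      p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
      s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
      h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
      a <- (n_bar / n_c) *
        (s2 - (1 / (n_bar - 1)) *
           (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
      b <- (n_bar / (n_bar - 1)) *
        (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
           ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
      cc <- h_bar / 2
      sum_a <- sum_a + a
      sum_abc <- sum_abc + a + b + cc
    }
  }
  sum_a / sum_abc
}

# Random two-population genotype matrix drawn in HW proportions from
# (possibly different) per-locus frequency lists.
random_two_pop_genotypes <- function(n1, n2, freqs1, freqs2 = freqs1,
                                     labels = c("source", "isolated")) {
  draw <- function(n, freqs)
    vapply(freqs, function(f)
      sample.int(length(f), n, replace = TRUE, prob = f), integer(n))
  a1 <- rbind(draw(n1, freqs1), draw(n2, freqs2))
  a2 <- rbind(draw(n1, freqs1), draw(n2, freqs2))
  genotype_matrix(a1, a2, rep(labels, c(n1, n2)))
}

# Mean of the truncated geometric stationary age distribution,
# P(a) proportional to s^a on 0..max_age.
truncated_geometric_mean <- function(s, max_age) {
  a <- 0:max_age
  w <- s^a
  sum(a * w) / sum(w)
}

# Quick simulation parameters for unit tests.
quick_params <- function(...) {
  args <- utils::modifyList(
    list(n_source = 60L, n_isolated = 20L, burn_in = 5L, horizon = 10L,
         subsample_size = 15L, n_replicates = 2L),
    list(...))
  do.call(sim_params, args)
}
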