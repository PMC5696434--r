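# Detection layer: the population-genetic statistics run on sampled
# genotypes.  Everything operates on a `genotype_matrix`, the common currency
# between the simulator and external data files.

#' Diploid multi-locus genotype matrix
#'
#' @param a1,a2 integer matrices (individuals x loci) holding the two allele
#'   IDs per locus; `NA` marks missing data (both alleles of a locus must be
#'   missing together).
#' @param pop population label per individual (coerced to factor).
#' @param loci locus names.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, pop, loci = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!identical(dim(a1), dim(a2)))
    stop("a1 and a2 must have identical dimensions")
  if (length(pop) != nrow(a1))
    stop("one population label per individual required")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("both or neither allele must be missing at a locus")
  if (any(a1 < 1L, na.rm = TRUE) || any(a2 < 1L, na.rm = TRUE))
    stop("allele IDs must be positive integers")
  loci <- loci %||% colnames(a1) %||% paste0("L", seq_len(ncol(a1)))
  # population levels keep their order of first appearance, so that the
  # simulator's (source, isolated) convention and file round-trips are
  # order-preserving
  if (!is.factor(pop)) pop <- factor(pop, levels = unique(pop))
  structure(list(a1 = a1, a2 = a2, pop = pop, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d individuals x %d loci; populations: %s\n",
              nrow(x$a1), ncol(x$a1),
              paste(sprintf("%s (%d)", levels(x$pop), table(x$pop)),
                    collapse = ", ")))
  invisible(x)
}

#' Multi-locus Weir-Cockerham FST (theta)
#'
#' The Weir & Cockerham (1984) variance-components estimator of Wright's
#' FST for the populations labelled in `g`.  For every allele at every locus
#' the among-population (a), among-individual-within-population (b) and
#' within-individual (c) components are computed from the sample sizes,
#' sample allele frequencies and observed heterozygote proportions; the
#' multi-locus estimate is the ratio of summed `a` components to summed
#' `a + b + c` across all alleles and loci.  Monomorphic loci contribute
#' nothing to either sum.  The estimator may legitimately be slightly
#' negative for undifferentiated samples.  Individuals missing a locus are
#' excluded from that locus only.
#'
#' @param g a [genotype_matrix] with at least two populations, each with at
#'   least two genotyped individuals per locus used.
#' @return the multi-locus theta (numeric scalar) with a `"per_locus"`
#'   attribute of per-locus estimates.  If every locus is monomorphic across
#'   the pooled sample, theta is undefined: `NA_real_` is returned with a
#'   warning, never a silent 0.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
fst_weir_cockerham <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- levels(droplevels(g$pop))
  r <- length(pops)
  if (r < 2L) stop("at least two populations required")
  L <- ncol(g$a1)
  sum_a <- 0; sum_abc <- 0
  per_locus <- rep(NA_real_, L)
  for (l in seq_len(L)) {
    keep <- !is.na(g$a1[, l])
    x1 <- g$a1[keep, l]; x2 <- g$a2[keep, l]
    popl <- droplevels(g$pop[keep])
    if (nlevels(popl) < r) next   # a population entirely missing this locus
    ni <- as.numeric(table(popl))
    if (any(ni < 2)) next
    alleles <- sort(unique(c(x1, x2)))
    if (length(alleles) < 2L) next
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    la <- 0; labc <- 0
    for (al in alleles) {
      # per-population allele frequency and heterozygote proportion
      pi <- (tapply(x1 == al, popl, sum) + tapply(x2 == al, popl, sum)) /
        (2 * ni)
      hi <- tapply((x1 == al) != (x2 == al), popl, mean)
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      la <- la + a; labc <- labc + a + b + cc
    }
    per_locus[l] <- if (labc != 0) la / labc else NA_real_
    sum_a <- sum_a + la; sum_abc <- sum_abc + labc
  }
  if (sum_abc == 0) {
    warning("theta is not estimable: all loci monomorphic across samples")
    theta <- NA_real_
  } else theta <- sum_a / sum_abc
  attr(theta, "per_locus") <- stats::setNames(per_locus, g$loci)
  theta
}

# Individuals x alleles count matrix (0/1/2 copies of each allele observed
# anywhere in the sample); missing loci give NA counts, imputed to the column
# mean by the DAPC pipeline.
allele_count_matrix <- function(g) {
  L <- ncol(g$a1)
  blocks <- lapply(seq_len(L), function(l) {
    alleles <- sort(unique(stats::na.omit(c(g$a1[, l], g$a2[, l]))))
    m <- vapply(alleles, function(al)
      (g$a1[, l] == al) + (g$a2[, l] == al), numeric(nrow(g$a1)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(g$a1))
    colnames(m) <- paste0(g$loci[l], ".", alleles)
    m
  })
  do.call(cbind, blocks)
}

#' DAPC misassignment between two labelled populations
#'
#' Discriminant analysis of principal components: each individual is encoded
#' as its vector of per-allele counts (0/1/2), columns are centred and
#' scaled, the leading principal components are retained, and a linear
#' discriminant is fit on the retained axes with the two population labels.
#' Every `focal`-population individual is assigned to the cluster with the
#' higher posterior; the statistic is the proportion of focal individuals
#' assigned to the other (reference) cluster.  As in common DAPC practice
#' the assigned individuals are the ones the discriminant was trained on.
#'
#' The default retention policy keeps the smallest number of PCs explaining
#' at least 90% of total variance, capped at n/3 axes to limit the
#' overfitting that drives spurious perfect reassignment.
#'
#' @param g a [genotype_matrix] with exactly two populations.
#' @param n_pcs number of principal components retained; `NULL` for the
#'   default policy.  Must be < n - 2.
#' @param focal label of the population whose individuals are checked
#'   (default the second level, `"isolated"` in simulator output).
#' @return proportion in `[0, 1]`, with attribute `"n_pcs"`.
#' @export
dapc_misassignment <- function(g, n_pcs = NULL, focal = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  pop <- droplevels(g$pop)
  if (nlevels(pop) != 2L) stop("exactly two populations required")
  focal <- focal %||% levels(pop)[2L]
  if (!focal %in% levels(pop)) stop("unknown focal population: ", focal)
  X <- allele_count_matrix(g)
  n <- nrow(X)
  # mean-impute missing counts (external data only; simulated data complete)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0))
    stop("degenerate genotypes: no variation among individuals")
  sds[sds == 0] <- 1
  Xs <- scale(X, center = TRUE, scale = sds)
  pc <- stats::prcomp(Xs, center = FALSE)
  keep_max <- sum(pc$sdev > 1e-8)
  if (is.null(n_pcs)) {
    cumvar <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    n_pcs <- min(which(cumvar >= 0.90), floor(n / 3), keep_max)
  }
  n_pcs <- max(1L, min(as.integer(n_pcs), keep_max, n - 3L))
  if (n_pcs >= n - 2L) stop("n_pcs must be smaller than n - 2")
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  is_focal <- pop == focal
  other <- setdiff(levels(pop), focal)
  # a PC with zero within-group variance but distinct group means separates
  # the groups perfectly; LDA is degenerate there, and every focal
  # individual is assigned to its own cluster
  wsd <- apply(scores, 2, function(x) sqrt(mean(tapply(x, pop, var))))
  degen <- wsd < 1e-9 * max(pc$sdev)
  if (any(degen)) {
    gap <- apply(scores[, degen, drop = FALSE], 2,
                 function(x) abs(diff(tapply(x, pop, mean))))
    if (any(gap > 1e-8)) {
      out <- 0
      attr(out, "n_pcs") <- n_pcs
      return(out)
    }
    scores <- scores[, !degen, drop = FALSE]
    if (ncol(scores) == 0L)
      stop("degenerate genotypes: no variation among individuals")
  }
  fit <- MASS::lda(scores, grouping = pop)
  post <- stats::predict(fit, scores)$posterior
  out <- mean(post[is_focal, other] > post[is_focal, focal])
  attr(out, "n_pcs") <- n_pcs
  out
}

#' Gibbs sampler for the Bayesian admixture model
#'
#' Fits the admixture clustering model: each of an individual's 2L allele
#' copies originates in one of K latent clusters; cluster allele frequencies
#' carry independent Dirichlet(lambda) priors per locus and individual
#' admixture proportions a symmetric Dirichlet(alpha) prior with alpha fixed
#' (not inferred).  The estimated log probability of the data, LnP(D), is
#' computed from the post-burn-in sweeps' observed-data log-likelihoods
#' ln P(X | P, Q) as mean - variance/2, the standard harmonic-style
#' estimator used for choosing K.
#'
#' @param g a [genotype_matrix].
#' @param k number of clusters (k = 1 is the panmictic baseline).
#' @param mcmc post-burn-in sweeps.
#' @param burnin discarded sweeps.
#' @param lambda Dirichlet prior mass per allele for cluster frequencies.
#' @param alpha Dirichlet prior mass per cluster for admixture proportions.
#' @return a list of class `admixture_fit`: `k`, `lnpd`, the posterior mean
#'   admixture matrix `q` (individuals x k, rows sum to 1), and the
#'   log-likelihood mean/variance over sweeps.
#' @export
admixture_loglik_sampler <- function(g, k, mcmc = 100000L, burnin = 100000L,
                                     lambda = 1, alpha = 1) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (k < 1L) stop("k must be >= 1")
  if (mcmc <= 0L || burnin <= 0L) stop("mcmc and burnin must be positive")
  enc <- encode_alleles(g)
  res <- admixture_gibbs_cpp(enc$alleles, enc$n_alleles, as.integer(k),
                             as.integer(mcmc), as.integer(burnin),
                             as.numeric(lambda), as.numeric(alpha))
  structure(list(k = as.integer(k), lnpd = res$lnpd, q = res$q,
                 loglik_mean = res$loglik_mean,
                 loglik_var = res$loglik_var),
            class = "admixture_fit")
}

# 0-based allele codes packed as an n x 2L integer matrix (-1 = missing),
# with per-locus allele counts, the layout the C++ sampler consumes.
encode_alleles <- function(g) {
  L <- ncol(g$a1)
  n <- nrow(g$a1)
  alleles <- matrix(-1L, n, 2L * L)
  n_alleles <- integer(L)
  for (l in seq_len(L)) {
    obs <- sort(unique(stats::na.omit(c(g$a1[, l], g$a2[, l]))))
    n_alleles[l] <- max(1L, length(obs))
    code <- function(x) {
      out <- match(x, obs) - 1L
      out[is.na(out)] <- -1L
      out
    }
    alleles[, 2L * l - 1L] <- code(g$a1[, l])
    alleles[, 2L * l] <- code(g$a2[, l])
  }
  list(alleles = alleles, n_alleles = n_alleles)
}

#' Choose the number of clusters by mean LnP(K)
#'
#' Runs `runs` independent samplers for each K in `1..k_max`, averages the
#' LnP(D) estimates within each K, and returns the K with the largest mean;
#' ties break toward the smaller (more parsimonious) K.
#'
#' @inheritParams admixture_loglik_sampler
#' @param k_max largest K tried.
#' @param runs independent sampler runs per K.
#' @return the selected K (integer), with attribute `"mean_lnpk"` (numeric
#'   vector indexed by K).
#' @export
best_k <- function(g, k_max = 3L, runs = 5L, mcmc = 100000L,
                   burnin = 100000L, lambda = 1, alpha = 1) {
  if (k_max < 1L) stop("k_max must be >= 1")
  mean_lnpk <- vapply(seq_len(k_max), function(k) {
    mean(vapply(seq_len(runs), function(i)
      admixture_loglik_sampler(g, k, mcmc, burnin, lambda, alpha)$lnpd,
      numeric(1)))
  }, numeric(1))
  if (any(!is.finite(mean_lnpk)))
    stop("non-finite mean LnP(K) encountered")
  out <- which.max(mean_lnpk)  # which.max returns the first (smallest) tie
  attr(out, "mean_lnpk") <- mean_lnpk
  out
}

#' Mean expected heterozygosity of a population
#'
#' He computed from the realized population allele frequencies at each locus
#' (`1 - sum(p^2)`), averaged over all loci including fixed ones (He = 0).
#'
#' @param pop a `drift_pop` object.
#' @return numeric scalar.
#' @export
mean_expected_heterozygosity <- function(pop) {
  if (pop_size(pop) == 0L) stop("empty population")
  mean(vapply(pop_allele_freqs(pop), function(p) 1 - sum(p^2), numeric(1)))
}
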