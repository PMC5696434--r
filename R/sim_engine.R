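# Agent-based, forward-time demographic and genetic core.
#
# A population is a fixed-size collection of diploid individuals carrying an
# age (in years since reproductive maturity) and one unordered allele pair
# per microsatellite locus.  Each simulated year, every individual survives
# with a fixed annual probability and is in any case removed once it passes
# the maximum age; every death is balanced the same year by a recruit of age
# 0 bred by random mating, so the census size never changes.  There is no
# mutation, selection, sex structure, or migration: drift is the only
# evolutionary force.
#
# Annual event order (documented so results are reproducible):
#   1. ages increment by one year;
#   2. individuals whose age now exceeds `max_age` die deterministically;
#   3. every other individual dies independently with probability
#      1 - annual_survival;
#   4. each death is replaced by one recruit of age 0.  The recruit's parents
#      are two distinct individuals drawn uniformly from the breeding pool --
#      all adults present at the start of the year, i.e. reproduction
#      precedes that year's mortality ("spawn, then die").  At every locus,
#      independently, the recruit inherits one uniformly chosen allele from
#      each parent (Mendelian inheritance).
#
# Breeding from the start-of-year pool rather than from the survivors keeps
# the model defined in complete-turnover regimes (short lifespans, low
# survival), where it converges to the discrete Wright-Fisher model; at the
# default 96% survival the two pools differ by ~4% of individuals and the
# dynamics are indistinguishable.

#' Simulation parameter bundle
#'
#' Collects every demographic and scheduling parameter of one simulation.
#' Defaults are the focal mussel system: a large contiguous source population
#' (census 1,000) stabilised for 75 years, an isolation event sampling 50
#' founders, 96% annual adult survival, a 62-year maximum age on the model
#' clock (maximum recorded lifespan 65 minus 3 years to maturity; the clock
#' starts at maturity, so `maturity_age` is carried for documentation only),
#' and a 400-year post-split horizon.
#'
#' @param n_source census size of the source population.
#' @param n_isolated census size of the isolated population.
#' @param annual_survival probability an individual survives one year.
#' @param max_age maximum age in years since maturity; individuals whose age
#'   exceeds it are removed.
#' @param maturity_age years from birth to reproductive maturity
#'   (documentation only; model time starts at maturity).
#' @param burn_in years the source population runs alone before the split.
#' @param horizon years simulated after the split.
#' @param n_replicates default number of replicates in grid runs.
#' @param subsample_size individuals sampled per population per analysis.
#' @param clustering_interval years between admixture-clustering analyses.
#' @return a validated object of class `sim_params`.
#' @export
sim_params <- function(n_source = 1000L, n_isolated = 50L,
                       annual_survival = 0.96, max_age = 62L,
                       maturity_age = 3L, burn_in = 75L, horizon = 400L,
                       n_replicates = 100L, subsample_size = 50L,
                       clustering_interval = 25L) {
  p <- list(n_source = as.integer(n_source),
            n_isolated = as.integer(n_isolated),
            annual_survival = as.numeric(annual_survival),
            max_age = as.integer(max_age),
            maturity_age = as.integer(maturity_age),
            burn_in = as.integer(burn_in), horizon = as.integer(horizon),
            n_replicates = as.integer(n_replicates),
            subsample_size = as.integer(subsample_size),
            clustering_interval = as.integer(clustering_interval))
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (!(p$annual_survival > 0 && p$annual_survival <= 1))
    stop("annual_survival must be in (0, 1]")
  if (p$max_age < 1L) stop("max_age must be >= 1")
  if (p$n_source <= 0L || p$n_isolated <= 0L)
    stop("population sizes must be positive")
  if (p$n_isolated > p$n_source)
    stop("n_isolated must not exceed n_source")
  if (p$subsample_size > min(p$n_source, p$n_isolated))
    stop("subsample_size must not exceed the smaller population")
  if (p$burn_in < 0L || p$horizon < 0L)
    stop("burn_in and horizon must be non-negative")
  if (p$clustering_interval < 1L) stop("clustering_interval must be >= 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, x[[nm]]))
  invisible(x)
}

# Stationary age distribution of the survival process: a recruit enters at
# age 0 and survives each year with probability s up to max_age, so the
# standing age distribution is the truncated geometric P(a) proportional to
# s^a, a = 0..max_age.
stationary_age_dist <- function(annual_survival, max_age) {
  w <- annual_survival^(0:max_age)
  w / sum(w)
}

#' Found a population in Hardy-Weinberg proportions
#'
#' Draws `n` diploid individuals whose two alleles at every locus are
#' independent draws from the founder frequencies, with ages drawn from the
#' stationary age distribution implied by the survival rule (truncated
#' geometric, P(age = a) proportional to `annual_survival^a`), so founding
#' introduces no demographic transient.
#'
#' @param freqs an [allele_freqs] object.
#' @param n census size.
#' @param params a [sim_params] object (survival and maximum age set the age
#'   distribution).
#' @param label population label.
#' @return an object of class `drift_pop`: integer allele matrices `a1`, `a2`
#'   (`n` rows, one column per locus), integer `age`, and the label.
#' @export
init_population <- function(freqs, n, params, label = "source") {
  stopifnot(inherits(freqs, "allele_freqs"))
  validate_sim_params(params)
  n <- as.integer(n)
  if (n <= 0L) stop("population size must be positive")
  L <- n_loci(freqs)
  draw <- function() vapply(unclass(freqs), function(f)
    sample.int(length(f), n, replace = TRUE, prob = f), integer(n))
  a1 <- draw(); a2 <- draw()
  if (n == 1L) { a1 <- matrix(a1, 1L); a2 <- matrix(a2, 1L) }
  age <- sample(0:params$max_age, n, replace = TRUE,
                prob = stationary_age_dist(params$annual_survival,
                                           params$max_age))
  new_drift_pop(a1, a2, as.integer(age), label,
                attr(freqs, "locus_names"))
}

new_drift_pop <- function(a1, a2, age, label, locus_names) {
  structure(list(a1 = a1, a2 = a2, age = age, label = label,
                 locus_names = locus_names),
            class = "drift_pop")
}

#' @export
print.drift_pop <- function(x, ...) {
  cat(sprintf("Population '%s': %d individuals, %d loci, mean age %.1f\n",
              x$label, nrow(x$a1), ncol(x$a1), mean(x$age)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a `drift_pop` object.
#' @export
pop_size <- function(pop) nrow(pop$a1)

#' Realized allele frequencies of a population
#'
#' @param pop a `drift_pop` object.
#' @return list of named frequency vectors, one per locus, over the alleles
#'   currently present (frequencies sum to 1).
#' @export
pop_allele_freqs <- function(pop) {
  n2 <- 2 * pop_size(pop)
  out <- lapply(seq_len(ncol(pop$a1)), function(l) {
    tab <- tabulate(c(pop$a1[, l], pop$a2[, l]))
    f <- tab[tab > 0] / n2
    names(f) <- which(tab > 0)
    f
  })
  names(out) <- pop$locus_names
  out
}

#' Advance a population by one year
#'
#' Applies the annual cycle (age increment, maximum-age cull, stochastic
#' mortality, same-year recruitment by random mating); see the event order
#' documented above.  Census size is invariant.
#'
#' @param pop a `drift_pop` object.
#' @param params a [sim_params] object.
#' @return the population one year later.
#' @export
advance_year <- function(pop, params) {
  n <- pop_size(pop)
  if (n == 0L) stop("cannot advance an empty population")
  L <- ncol(pop$a1)
  age <- pop$age + 1L
  dead <- (age > params$max_age) |
    (stats::runif(n) < 1 - params$annual_survival)
  nd <- sum(dead)
  if (nd > 0L) {
    if (n < 2L)
      stop("simulation error: a death occurred but the breeding pool has ",
           "fewer than two adults, so no parent pair can be formed")
    # two distinct parents per recruit, drawn (with replacement across
    # recruits) from the start-of-year population
    p1 <- sample.int(n, nd, replace = TRUE)
    p2 <- sample.int(n, nd, replace = TRUE)
    while (any(clash <- p1 == p2))
      p2[clash] <- sample.int(n, sum(clash), replace = TRUE)
    pick1 <- matrix(stats::runif(nd * L) < 0.5, nd, L)
    pick2 <- matrix(stats::runif(nd * L) < 0.5, nd, L)
    g1 <- pop$a1[p1, , drop = FALSE]
    g1[!pick1] <- pop$a2[p1, , drop = FALSE][!pick1]
    g2 <- pop$a1[p2, , drop = FALSE]
    g2[!pick2] <- pop$a2[p2, , drop = FALSE][!pick2]
    pop$a1[dead, ] <- g1
    pop$a2[dead, ] <- g2
    age[dead] <- 0L
  }
  pop$age <- age
  pop
}

#' Simulate an isolation event
#'
#' Samples `n_isolated` founders uniformly without replacement from the
#' source population and copies them into a new population.  The source is
#' left unchanged: it stands for an effectively unbounded downstream
#' population, so the founders are copied rather than removed.  After the
#' split the two populations evolve with zero gene flow.
#'
#' @param source a `drift_pop` object.
#' @param n_isolated number of founders.
#' @param label label of the new population.
#' @return the isolated `drift_pop`.
#' @export
split_isolated <- function(source, n_isolated, label = "isolated") {
  n_isolated <- as.integer(n_isolated)
  if (n_isolated > pop_size(source))
    stop("n_isolated (", n_isolated, ") exceeds source size (",
         pop_size(source), ")")
  if (n_isolated <= 0L) stop("n_isolated must be positive")
  idx <- sample.int(pop_size(source), n_isolated)
  new_drift_pop(source$a1[idx, , drop = FALSE],
                source$a2[idx, , drop = FALSE],
                source$age[idx], label, source$locus_names)
}

#' Analysis schedule and scale knobs for a replicate
#'
#' Controls which statistics are computed when during [run_replicate()].
#' The published experimental design computes FST and DAPC misassignment
#' every year and runs the admixture clusterer every `clustering_interval`
#' years with MCMC 100,000 after a 100,000-sweep burn-in and 5 runs per K;
#' those are the defaults.  Desk-scale runs shrink `mcmc`, `burnin`, `runs`
#' and restrict `stat_years` / `clustering_years` to the years actually
#' reported.
#'
#' @param stat_years years (0 = split time) at which FST and DAPC are
#'   computed; `NULL` means every year.
#' @param clustering_years years at which the admixture clusterer runs;
#'   `NULL` means year 0 and every `clustering_interval` years.
#' @param do_clustering disable clustering entirely (it dominates runtime).
#' @param k_max largest number of clusters tried.
#' @param runs independent sampler runs per K.
#' @param mcmc post-burn-in Gibbs sweeps per run.
#' @param burnin discarded sweeps per run.
#' @param n_pcs PCA axes retained for DAPC; `NULL` for the default policy
#'   (smallest number explaining 90% variance, capped at n/3).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(stat_years = NULL, clustering_years = NULL,
                            do_clustering = TRUE, k_max = 3L, runs = 5L,
                            mcmc = 100000L, burnin = 100000L, n_pcs = NULL) {
  structure(list(stat_years = stat_years,
                 clustering_years = clustering_years,
                 do_clustering = isTRUE(do_clustering),
                 k_max = as.integer(k_max), runs = as.integer(runs),
                 mcmc = as.integer(mcmc), burnin = as.integer(burnin),
                 n_pcs = n_pcs),
            class = "analysis_config")
}

#' Run one seeded replicate of the isolation experiment
#'
#' Founds the source population, stabilises it for `burn_in` years, samples
#' the isolated population, then advances both for `horizon` years with zero
#' gene flow.  Mean expected heterozygosity of each population is recorded
#' every year; Weir-Cockerham FST and DAPC misassignment between fresh
#' subsamples of `subsample_size` individuals per population are recorded at
#' the scheduled statistic years (year 0 = split time); the admixture
#' clusterer's chosen K is recorded at the scheduled clustering years.  The
#' whole trajectory is reproducible from `seed`.
#'
#' @param params a [sim_params] object.
#' @param freqs founder frequencies ([allele_freqs]); default the packaged
#'   downstream-site profile.
#' @param seed integer seed for this replicate.
#' @param analysis an [analysis_config] object.
#' @return an object of class `replicate_trace`: `yearly` (data.frame with
#'   columns year, he_source, he_isolated, theta, dapc_misassignment; the
#'   last two are NA off-schedule) and `clustering` (data.frame with columns
#'   year, best_k), plus the seed and parameters.
#' @export
run_replicate <- function(params, freqs = founder_profile(), seed = 1L,
                          analysis = analysis_config()) {
  validate_sim_params(params)
  set.seed(as.integer(seed))
  stat_years <- analysis$stat_years %||% 0:params$horizon
  clust_years <- analysis$clustering_years %||%
    seq(0L, params$horizon, by = params$clustering_interval)
  if (!analysis$do_clustering) clust_years <- integer(0)

  src <- init_population(freqs, params$n_source, params, "source")
  for (y in seq_len(params$burn_in)) src <- advance_year(src, params)
  iso <- split_isolated(src, params$n_isolated)

  years <- 0:params$horizon
  yearly <- data.frame(year = years,
                       he_source = NA_real_, he_isolated = NA_real_,
                       theta = NA_real_, dapc_misassignment = NA_real_)
  cy <- intersect(clust_years, years)
  clustering <- data.frame(year = cy, best_k = rep(NA_integer_, length(cy)))

  record <- function(y) {
    i <- match(y, years)
    yearly$he_source[i] <<- mean_expected_heterozygosity(src)
    yearly$he_isolated[i] <<- mean_expected_heterozygosity(iso)
    if (y %in% stat_years || y %in% clustering$year) {
      g <- subsample_genotypes(src, iso, params$subsample_size)
      if (y %in% stat_years) {
        yearly$theta[i] <<- fst_weir_cockerham(g)
        yearly$dapc_misassignment[i] <<-
          dapc_misassignment(g, n_pcs = analysis$n_pcs)
      }
      if (y %in% clustering$year)
        clustering$best_k[match(y, clustering$year)] <<-
          best_k(g, k_max = analysis$k_max, runs = analysis$runs,
                 mcmc = analysis$mcmc, burnin = analysis$burnin)
    }
  }

  record(0L)
  for (y in seq_len(params$horizon)) {
    src <- advance_year(src, params)
    iso <- advance_year(iso, params)
    record(y)
  }
  structure(list(seed = as.integer(seed), params = params,
                 yearly = yearly, clustering = clustering),
            class = "replicate_trace")
}

#' @export
print.replicate_trace <- function(x, ...) {
  cat(sprintf(
    "Replicate trace (seed %d): Nc=%d, max age %d, %d years post-split\n",
    x$seed, x$params$n_isolated, x$params$max_age, x$params$horizon))
  done <- !is.na(x$yearly$theta)
  if (any(done)) {
    last <- max(x$yearly$year[done])
    cat(sprintf("  final scheduled year %d: theta = %.4f, DAPC misassignment = %.3f\n",
                last, x$yearly$theta[x$yearly$year == last],
                x$yearly$dapc_misassignment[x$yearly$year == last]))
  }
  invisible(x)
}

#' Draw per-population subsamples as a genotype matrix
#'
#' Samples `n_per_pop` individuals without replacement from each population
#' (fresh each call) and stacks them into a [genotype_matrix] with the two
#' population labels, the unit of data every detection statistic consumes.
#'
#' @param pop_a,pop_b `drift_pop` objects.
#' @param n_per_pop individuals per population.
#' @return a [genotype_matrix].
#' @export
subsample_genotypes <- function(pop_a, pop_b, n_per_pop) {
  n_per_pop <- as.integer(n_per_pop)
  if (n_per_pop > pop_size(pop_a) || n_per_pop > pop_size(pop_b))
    stop("subsample size exceeds a population size")
  ia <- sample.int(pop_size(pop_a), n_per_pop)
  ib <- sample.int(pop_size(pop_b), n_per_pop)
  genotype_matrix(
    a1 = rbind(pop_a$a1[ia, , drop = FALSE], pop_b$a1[ib, , drop = FALSE]),
    a2 = rbind(pop_a$a2[ia, , drop = FALSE], pop_b$a2[ib, , drop = FALSE]),
    pop = rep(c(pop_a$label, pop_b$label), each = n_per_pop),
    loci = pop_a$locus_names)
}
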