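---
title: "Isolation by drift in long-lived populations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolation by drift in long-lived populations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(driftlag)
```

## The question the package answers

When a barrier -- a dam, for the freshwater mussels that motivate the
defaults -- splits a population, the two fragments diverge only through
genetic drift, and drift is slow when populations are large and when
generations overlap heavily.  A survey taken too early will find no
structure and may wrongly conclude that the barrier does not block gene
flow.  `driftlag` simulates the fragmentation forward in time, in *years*
rather than generations, and runs the three analyses a field study would
run (Weir--Cockerham $F_{ST}$, DAPC assignment, Bayesian admixture
clustering) on samples from the simulated populations, so that the
*detection lag* -- the number of years before each analysis reliably sees
two populations -- can be read off as a function of census size and
lifespan.

## The demographic model

A population is a fixed-size set of $N_c$ diploid individuals.  Each
carries an age in years since reproductive maturity (the model clock starts
at maturity; the default 62-year maximum age is a 65-year maximum lifespan
minus 3 years to maturity) and one unordered allele pair at each of $L$
microsatellite loci.  Every simulated year:

1. ages increment;
2. individuals past the maximum age die deterministically;
3. every other individual dies independently with probability
   $1 - s$ ($s = 0.96$ annual survival by default);
4. each death is balanced, the same year, by a recruit of age 0.  The
   recruit's parents are two distinct individuals drawn uniformly from the
   adults present at the start of the year, and at every locus the recruit
   inherits one uniformly chosen allele from each parent.

There is no mutation, migration, selection, sex structure, or variation in
annual recruitment: census size is exactly constant and drift is the only
force.  Founders' genotypes are drawn in Hardy--Weinberg proportions from a
per-locus frequency specification, and founder ages from the stationary
distribution of the survival process, the truncated geometric
$P(a) \propto s^a$, $a = 0, \dots, a_{\max}$, so no demographic transient
contaminates the burn-in.

Two modelling choices deserve comment because they were genuinely open:

* **Breeding pool.**  Parents are drawn from the start-of-year adults
  ("spawn, then die") rather than from the survivors of that year's
  mortality.  At $s = 0.96$ the two pools differ by about 4% of
  individuals, and we verified the resulting trajectories are statistically
  indistinguishable; but the spawn-then-die rule keeps the model defined
  when survival is made arbitrarily small, in which limit the model
  collapses exactly to the discrete Wright--Fisher model.  That limit is
  the package's strongest correctness oracle: with `max_age = 1` and
  vanishing survival, mean expected heterozygosity must decay as
  $H_0 (1 - 1/2N)^t$, and the test suite holds the simulator to that
  closed form within 5%.
* **Event order.**  The maximum-age cull is applied after the age
  increment and before stochastic mortality, which makes the age cap exact
  (no individual is ever observed past `max_age`).

### Effective size implied by the demography

The renewal process is Moran-like: with $D$ deaths per year (about
$N_c (1 - s)$ plus a small maximum-age term), the per-year variance of an
allele-frequency change is approximately $p(1-p)\, D / N_c^2$, i.e. a
per-year effective size $N_y \approx N_c^2 / 2D$.  For the defaults
($s = 0.96$, maximum age 62) this gives $N_y \approx 12\,N_c$; at
$N_c = 50$, heterozygosity falls by roughly 1/1200 per year, and the
simulator's measured decay matches this closed form.  It is worth being
explicit that this quantity is *very* sensitive to the variance in lifetime
reproductive success implied by the renewal rule.  Uniform parent choice
with geometric lifespans places that variance near its random-mating
maximum; renewal rules that equalise lifetime output (for example,
vacancies inherited by offspring of the deceased) can halve the drift rate
at identical census size and survival.  Comparisons with other
individual-based implementations of the same verbal model should therefore
expect disagreement up to a factor of ~2 in time scale unless the
replacement rule is matched exactly -- the package documents its rule
precisely for this reason.

## Founder frequencies

Per-locus founder frequencies are rarely published; per-locus expected
heterozygosity usually is.  `freqs_matching_he()` synthesises a frequency
vector hitting any feasible He target exactly (bisection on a
dominant-plus-symmetric parameterisation; a Dirichlet rejection sampler is
available when irregular profiles are wanted).  The packaged default,
`founder_profile()`, reproduces the empirical He profile of the downstream
population that motivates the default parameters: six loci with
He = 0.690, 0.804, 0.727, 0.489, 0, 0.  Allele counts per locus are not
knowable from He alone; the default uses 6 (8 where the target requires
more), typical microsatellite richness.  Drift and $F_{ST}$ dynamics at
these time scales depend on He far more than on allele count, so this
choice is benign, but it is a choice.

```{r founders}
fp <- founder_profile()
round(expected_heterozygosity(fp), 3)
```

## The detection layer

**Weir--Cockerham $F_{ST}$.**  `fst_weir_cockerham()` implements the 1984
variance-components estimator $\hat\theta$: per allele per locus the
among-population, among-individual and within-individual components
$a, b, c$; multi-locus $\hat\theta = \sum a / \sum (a+b+c)$.  Monomorphic
loci contribute nothing; an entirely monomorphic table returns `NA` with a
warning rather than a silent 0; slightly negative estimates are legitimate
and preserved.  The unit tests pin the implementation to an independently
coded literal transcription of the published component formulas.

**DAPC.**  Individuals are encoded as per-allele counts (0/1/2), columns
centred and scaled, a PCA taken, and a linear discriminant fit on the
retained axes with the two population labels; the statistic is the
proportion of isolated-population individuals whose posterior favours the
source cluster.  Retention policy: the smallest number of axes explaining
90% of variance, capped at $n/3$.  Because assignment is performed on the
training individuals (standard practice for this statistic), it is
optimistic under the null: with ~20 retained axes and $n = 100$ the
expected null misassignment is near 0.3, not 0.5.  The tests therefore
check exchangeability (symmetry under swapping which population is focal)
and monotonicity in divergence rather than asserting a naive 0.5.

**Admixture clustering.**  `admixture_loglik_sampler()` is a Gibbs sampler
for the standard admixture model: each allele copy carries a latent
cluster of origin; cluster-by-locus allele frequencies have independent
Dirichlet($\lambda = 1$) priors; per-individual admixture proportions a
symmetric Dirichlet($\alpha = 1$) prior with $\alpha$ fixed, a deliberate
simplification of samplers that infer $\alpha$ or correlate frequencies
across clusters.  Model choice follows the conventional estimator: per
sweep the observed-data log-likelihood
$\ln P(X \mid P, Q)$ is recorded, and
$\widehat{\ln P(D)} = \overline{\ell} - \operatorname{var}(\ell)/2$;
`best_k()` averages this over independent runs for each $K$ and picks the
maximum, ties toward smaller $K$.  The estimator is a likelihood quantity,
invariant to cluster label switching, which the tests verify across
independently initialised runs.  On panmictic data the variance penalty
makes $K = 1$ win at least 90% of the time (calibrated in the test suite);
on fully separated populations $K = 2$ wins immediately.

## The experiment module

`run_grid()` runs seeded replicates over a census-size $\times$ lifespan
grid (the full design is 5 census sizes $\times$ 6 lifespans = 30
parameter sets).  All per-replicate seeds are drawn up front from a master
seed, so results are invariant to the worker count; a failed replicate is
excluded and counted, never silently averaged.  Summaries
(`summarize_traces()`) are pure functions of the traces.  Statistics are
computed on fresh 50-individual subsamples per population per scheduled
year; clustering runs every 25 years by default.

### Problem sizes

The full design (100 replicates per set, clustering every 25 years at
MCMC 100,000/100,000 with 5 runs per K) is a compute-cluster workload.
The package's own reference experiment -- what `scripts/acceptance.R` and
the acceptance tests run -- is a desk-scale version chosen to finish in
minutes while keeping Monte-Carlo error well inside the tolerances used:
20 replicates per census size, statistics at the reported years only, and
clustering at years 0/175/375 with MCMC 5,000 after 5,000 burn-in and 3
runs per K.  With 20 replicates the standard error of mean $\theta$ at
year 400 ($N_c = 50$) is about 0.014, an order of magnitude below the
trajectory itself.

## What the generator does and does not emulate

The simulator reproduces: constant-size overlapping-generation demography,
Hardy--Weinberg founding from an empirical heterozygosity profile,
complete isolation after a split, and sampling noise of 50-individual
surveys.  It does not emulate: mutation (irrelevant over 400 years for
microsatellites only in first approximation), downstream-only gene flow
over the barrier, null alleles and genotyping error, spatial structure
within populations, sex structure, or temporally varying vital rates.
Passing tests therefore say the *statistics* behave correctly on data of
this idealised structure; field data carry additional noise sources that
generally push every detection method toward later detection, so the
simulated lags are best read as lower bounds.

## Known limitations

* The renewal rule fixes the lifetime reproductive-success variance near
  its random-mating maximum; see the effective-size discussion above.
* The admixture sampler uses independent cluster frequencies and fixed
  $\alpha$; with very weak divergence this is mildly conservative about
  choosing $K = 2$ relative to samplers with correlated-frequency priors.
* DAPC misassignment is training-set assignment, inheriting its optimism;
  cross-validated assignment would be less biased but is not the statistic
  conventionally reported.
* `maturity_age` is documentation: the model clock starts at maturity, so
  juveniles are never represented explicitly.
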