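# driftlag

Forward-time, agent-based simulation of genetic drift after a fragmentation
event, for species where the interesting clock ticks in **years, not
generations** — long-lived organisms with strongly overlapping generations,
such as freshwater mussels isolated by a dam.  The package answers the
question a conservation geneticist faces when a survey across an obvious
barrier finds no structure: *has enough time passed for drift to make the
isolation visible at all?*

It is aimed at population geneticists and conservation practitioners who
want to simulate a specific system (census size, lifespan, survival rate,
marker heterozygosities) and read off the expected detection lag of the
three analyses a field study would actually run.

## Model and statistics

* **Demography.**  A population is a fixed-size set of `N_c` diploid
  individuals with ages in years since maturity.  Annually: ages increment;
  individuals past `max_age` die; others die with probability `1 - s`
  (default `s = 0.96`); each death is replaced the same year by an age-0
  recruit bred by random mating (two distinct uniform parents, one
  uniformly chosen allele from each at every locus).  No mutation,
  selection, migration, or sex structure — drift alone.
* **Experiment.**  A source population (`N = 1000`) founded in
  Hardy–Weinberg proportions from per-locus allele frequencies runs 75
  years; an isolation event copies `N_c ∈ {50 … 500}` founders into an
  isolated population; both run 400 more years with zero gene flow, sampled
  by fresh 50-individual subsamples per analysis year.
* **Detection.**  Weir–Cockerham (1984) multi-locus θ; DAPC assignment
  (allele-count PCA + LDA, the proportion of isolated individuals assigned
  to the source cluster); and a Gibbs sampler for the Bayesian admixture
  model with model choice by mean estimated ln P(D) over independent runs
  (`K` maximising it; ties to the smaller `K`).
* **Founders.**  Published per-locus expected heterozygosities stand in
  for unpublished frequencies: `freqs_matching_he()` synthesises frequency
  vectors hitting an He target exactly; the packaged profile has
  He = 0.690, 0.804, 0.727, 0.489, 0, 0 across six microsatellite loci.

See `vignettes/detection-lag.Rmd` for the full model description,
parameter meanings, numerical choices, and limitations.

## Worked example

One replicate of the focal scenario (`N_c = 50`, maximum age 62), with
statistics every 100 years and clustering at years 0/200/400:

```r
library(driftlag)
params <- sim_params(n_isolated = 50, max_age = 62)
trace <- run_replicate(
  params, founder_profile(), seed = 42,
  analysis = analysis_config(stat_years = c(0, 100, 200, 300, 400),
                             clustering_years = c(0, 200, 400),
                             runs = 3, mcmc = 5000, burnin = 5000))
subset(trace$yearly, year %in% c(0, 100, 200, 300, 400))
#>     year he_source he_isolated        theta dapc_misassignment
#> 1      0 0.4538828   0.4512000 -0.004609529               0.38
#> 101  100 0.4524713   0.4303000  0.020890287               0.14
#> 201  200 0.4653654   0.3643000  0.068244794               0.06
#> 301  300 0.4618920   0.3250667  0.082492459               0.06
#> 401  400 0.4607187   0.3163667  0.116697223               0.00
trace$clustering
#>   year best_k
#> 1    0      1
#> 2  200      2
#> 3  400      2
```

Reading it: at the split (year 0) the two samples are exchangeable — θ is
indistinguishable from 0, DAPC misassigns nearly 40% of individuals
(its training-assignment null), and the admixture model correctly prefers
a single cluster.  Drift then moves every statistic monotonically: θ
climbs to ~0.12, the isolated population's heterozygosity erodes from
0.45 to 0.32 while the large source barely moves, and from year 200 the
clusterer resolves two populations.

External data work the same way through the GENEPOP reader:

```r
g <- read_genepop(system.file("extdata", "two_pop_synthetic.gen",
                              package = "driftlag"))
fst_weir_cockerham(g)        # 0.1311
dapc_misassignment(g)        # 0.033
best_k(g, k_max = 3, runs = 3, mcmc = 5000, burnin = 5000)  # 2
```

Grid experiments (`run_grid()`) aggregate replicate traces into trajectory
and detection-frequency tables, serialised with `write_grid_csvs()`; a thin
command-line front end lives in `inst/cli/driftlag` (subcommands
`simulate`, `grid`, `analyze`, `founders`).

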