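# Builds the small plain-text fixtures shipped under inst/extdata.
# Run from the package root with the package installed.

library(driftlag)

# Synthetic founder frequency table reproducing the published per-locus
# expected heterozygosities of the downstream (LG) site.
write_allele_freqs(founder_profile(),
                   "inst/extdata/founders_downstream_lg_synthetic.csv")

# A synthetic two-population GENEPOP file at a known, appreciable divergence:
# source vs isolated population (Nc = 50, max age 22) sampled 150 years after
# the split, 30 individuals per population.
set.seed(20170)
p <- sim_params(n_isolated = 50, max_age = 22, horizon = 150,
                subsample_size = 30)
src <- init_population(founder_profile(), p$n_source, p)
for (y in seq_len(p$burn_in)) src <- advance_year(src, p)
iso <- split_isolated(src, p$n_isolated)
for (y in seq_len(p$horizon)) {
  src <- advance_year(src, p)
  iso <- advance_year(iso, p)
}
g <- subsample_genotypes(src, iso, 30)
write_genepop(g, "inst/extdata/two_pop_synthetic.gen",
              title = "synthetic two-population sample (150 y divergence)")
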