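# fursealpop

Population genomics of a heavily exploited, rapidly recolonizing fur
seal, as an R package. `fursealpop` is aimed at conservation geneticists
working with SNP genotype matrices from multi-colony pinniped (or
similarly structured) sampling designs, where differentiation is subtle
(pairwise FST of order 10⁻³–10⁻²), the demographic history contains
severe anthropogenic bottlenecks, and a practical goal is assigning
individuals — for example fisheries bycatch — back to their colony or
region of origin.

The package covers the full analysis chain:

- **Genotype I/O and QC** — PLINK text PED/MAP and VCF readers/writers;
  a five-step filter chain (individual missingness > 0.9, locus
  missingness > 0.2, MAF < 0.05, per-colony Hardy–Weinberg exact tests,
  within-colony LD pruning, the last two removing a locus only when ≥ 6
  of 8 colonies flag it).
- **Diversity and structure** — Ho, unbiased He, FIS with gamete
  re-pairing permutation tests; pairwise Weir–Cockerham θ with Slatkin's
  linearization θ/(1−θ); Mantel isolation-by-distance tests against
  great-circle distances; three-level AMOVA with Φ-statistics; plain
  PCA.
- **Coalescent simulation** — unlinked biallelic SNPs (one mutation per
  genealogy, pooled-MAF ascertainment) under piecewise-constant
  two-deme bottleneck scenarios and a finite-island model.
- **ABC demographic inference** — uniform priors with ordering
  conditions over the two-bottleneck recolonization history
  (pre-human ≈ 10⁶-scale population → Polynesian-era decline →
  European-era collapse into a refugium of order 10² → recolonization
  and north/south divergence), DIYABC-style summary statistics,
  rejection sampling, direct and logistic model choice against a
  constant-size null, Beaumont local-linear posterior adjustment, and
  type I/II error estimation from pseudo-observed datasets.
- **Outlier scanning** — FDIST-style FST-vs-He scan with an
  island-model null, rank-based p-values, Benjamini–Hochberg q-values
  and confidence envelopes.
- **Assignment** — leave-one-out home-likelihood assignment to colonies
  or clusters with the 0.005 zero-frequency substitution, Monte-Carlo
  home p-values, and per-panel accuracy comparisons.
- **Synthetic studies** — a seeded Balding–Nichols generator emulating
  the eight-colony, 167-pup design (two clusters plus an admixture
  zone, mean He ≈ 0.26, pairwise θ ≈ 0.003–0.02), so everything runs
  end-to-end without external data.

Results come back as tibbles (with `tidy()`/`glance()` methods on
fitted objects and `autoplot()` for the main result types), so the
package drops into dplyr/ggplot2 workflows.

## Worked example

```r
library(fursealpop)

# A synthetic eight-colony study in the published design: 167 pups,
# three clusters, admixture zone at the CP/OP-analogue colonies.
study <- generate_study(synth_config(n_loci = 2000, seed = 11))
g <- study$genotypes
pops <- study$pops

qc <- apply_qc(g, pops, qc_config())
qc$report
#> # A tibble: 5 x 5
#>   step                   n_individuals_removed n_loci_removed n_individuals n_loci
#>   <chr>                                  <int>          <int>         <int>  <int>
#> 1 individual_missingness                     0              0           167   2000
#> 2 locus_missingness                          0              0           167   2000
#> 3 maf                                        0            195           167   1805
#> 4 hwe                                        0              0           167   1805
#> 5 ld                                         0              0           167   1805

heterozygosity(qc$genotypes, pops, "cluster")
#> # A tibble: 3 x 4
#>   group             n    Ho    He
#>   <chr>         <int> <dbl> <dbl>
#> 1 NZ-North-East    29 0.283 0.283
#> 2 NZ-North-West    72 0.282 0.282
#> 3 NZ-South         66 0.282 0.283

fst <- pairwise_fst(qc$genotypes, pops)
round(fst$linearized["OBI", c("CF", "CP", "HB")], 4)
#>     CF     CP     HB
#> 0.0022 0.0058 0.0165

ibd_test(fst, pops, n_perm = 999, seed = 1)
#> # A tibble: 1 x 4
#>       r      p n_perm undefined
#>   <dbl>  <dbl>  <dbl> <lgl>
#> 1 0.443  0.039    999 FALSE
```

The He values sit in the intended low-diversity regime (the MAF filter
raises them slightly above the raw 0.26 generator target), the
linearized FST values show the weak within-cluster (OBI-CF, ~0.002)
versus between-cluster (OBI-HB, ~0.017) contrast with the
admixture-zone colony (CP) in between, and the Mantel test finds the
weak but significant isolation-by-distance gradient that the
geographically segregated clusters induce.

Demographic inference against the constant-size null, at desk scale:

```r
scen <- fur_seal_scenarios()
tab <- build_reference_table(scen, n_N = 101, n_S = 66,
                             sim_config(n_loci = 1000),
                             n_per_scenario = 5000, seed = 1)
obs_data <- simulate_dataset(
  build_two_decline_scenario(
    do.call(scenario_params, fur_seal_posterior_modes()), 101, 66),
  sim_config(n_loci = 1000, seed = 2))
obs <- summary_stats(obs_data$genotypes, obs_data$pops, c("NZ-N", "NZ-S"))
rej <- abc_reject(tab, obs, tolerance = 0.01)
model_choice(rej)

post <- adjust_posterior(rej, fur_seal_priors(), scenario = "two_decline")
posterior_summary(post)
```

Assignment of individuals back to their colonies:

```r
res <- assign_individuals(qc$genotypes, pops, level = "colony",
                          cfg = assign_config(seed = 1))
glance(res)
res$accuracy
```

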