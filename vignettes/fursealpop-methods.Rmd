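---
title: "Population-genomic inference for a recolonizing fur seal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic inference for a recolonizing fur seal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fursealpop)
```

## The scientific problem

The New Zealand fur seal (*Arctocephalus forsteri*) was hunted close to
extinction twice — first during Polynesian settlement, then by the
19th-century European sealing industry — and has since recolonized most of
its former range from a small number of refugial colonies. Two questions
follow for anyone managing such a species with SNP data from pup samples
across its breeding colonies:

1. **How much population structure is left?** Rapid recolonization by a
   highly vagile species homogenizes allele frequencies, so colony
   differentiation is expected to be subtle (pairwise FST of order
   10^-3^–10^-2^), with perhaps a weak gradient between a north-western
   and a southern cluster and an admixture zone between them.
2. **Can the demographic collapse be read from the genomes, and can
   individuals (e.g. fisheries bycatch) be traced to their colony or
   region of origin?**

`fursealpop` implements the full analysis chain for these questions: SNP
quality control, diversity and differentiation statistics, hierarchical
AMOVA, isolation-by-distance testing, a coalescent simulator for
two-bottleneck demographic scenarios, approximate Bayesian computation
(ABC) for model choice and parameter estimation, an FDIST-style
FST-outlier scan, and leave-one-out likelihood assignment. A seeded
synthetic-study generator emulates the sampling design (eight colonies,
14–28 pups each, 167 individuals) so the whole pipeline runs end-to-end
with no external data.

## Genotype model and quality control

Genotypes are biallelic SNP dosages (copies of the alternate allele,
missing allowed) in an individuals-by-loci matrix. The QC chain applies,
in order: individual missingness (default: drop individuals missing more
than 90% of calls), locus missingness (drop loci missing in more than 20%
of individuals), minor allele frequency (drop MAF < 5%, recomputed after
the missingness filters), a per-colony Hardy–Weinberg exact test, and
within-colony linkage-disequilibrium pruning. The HWE and LD filters
remove a locus only when at least six of the eight colonies flag it — a
deliberate guard against removing loci that merely drift out of
equilibrium in one small colony.

Two thresholds are not fixed by the programs the field commonly uses and
were set here explicitly: the per-colony HWE significance level
(`hwe_alpha = 0.01`; conservative because per-colony samples are small)
and the LD rule (sliding window of 50 loci, flag pairs with r² > 0.8,
keep the better-called member; a pairwise-vs-window choice is exposed
through the window width). The HWE test enumerates every heterozygote
count consistent with the observed allele counts and sums the
probabilities of configurations no more likely than the observed one; it
is checked in the test suite against an independent factorial-formula
oracle for every genotype triple with up to 20 individuals.

## Diversity, differentiation, AMOVA, IBD

Expected heterozygosity uses the unbiased estimator
$\hat H_e = \frac{2n}{2n-1}\,2\hat p(1-\hat p)$ per locus (which of the
biased or unbiased variants the field's standard software averages is not
always stated; unbiased is used here and is configurable in spirit by
post-processing). FIS is $1 - \bar H_o / \bar H_e$ on multilocus means,
tested by re-pairing gametes within the group, which leaves $H_e$
invariant and resamples $H_o$. Pairwise FST is the Weir–Cockerham (1984)
variance-components estimator θ, combined across loci by ratio of sums;
negative estimates are reported as such. Slatkin's linearization
θ/(1−θ) is applied for the isolation-by-distance Mantel test against
great-circle distances between colony coordinates (coordinates are not
part of published colony tables; the synthetic design carries plausible
ones, and users of real data must supply their own). All permutation
p-values use (k+1)/(n+1) smoothing, so no p-value is ever exactly zero.

The three-level AMOVA (among groups, among colonies within groups, within
colonies) operates on squared differences of allele dosage summed over
loci — the natural distance for unphased SNPs — with mean imputation of
missing dosages, and reports Φ-statistics with permutation tests at each
level. Components are validated against an independent centroid-deviation
oracle; percentages sum to 100 within 10^-6^.

PCA mean-imputes missing dosages per locus, centres columns, and
eigendecomposes the individual covariance matrix. It is deliberately
plain: read-depth-aware relationship-matrix methods are out of scope.

## The coalescent simulator

Each SNP locus is an independent Kingman coalescent. Within a deme of
diploid size $N$, each lineage pair coalesces at rate $1/(2N)$ per
generation (the continuous-time approximation of the Wright–Fisher
model — appropriate because sizes are far larger than samples). The
two-deme scenarios place two isolated demes (no migration after
divergence, matching the recolonization-then-divergence structure) that
merge backward in time into an ancestral deme with piecewise-constant
sizes. A single mutation is placed on the tree with probability
proportional to branch length; gene copies below it carry the derived
allele. Loci are redrawn whole until the pooled-sample minor allele
frequency reaches the ascertainment threshold (default 5%, cap 10,000
redraws) — the simplest faithful reading of Hudson-style SNP sampling.
Gene copies are paired at random into diploids within demes. Times are
generations throughout; the 7-year generation time only annotates
reports in years.

The two-decline scenario has, backward in time: contemporary northern and
southern demes (sizes `Ne_NZ_N`, `Ne_NZ_S`) until `t_post_seal`; the
post-sealing refugium (`Ne_refugium`) until `t_Europeans`; the historical
population (`Ne_historical_NZ`) until `t_Polynesian`; and the pre-human
population (`Ne_pre_historical`) beyond. Default priors are uniform:
sizes 10²–10⁴ (contemporary), 10²–2.5×10³ (refugium), 10³–5×10⁶
(historical and pre-human); times 100–200, 25–50 and 1–25 generations,
with the orderings `t_Polynesian > t_Europeans > t_post_seal` and the
pre-human size exceeding both contemporary sizes. The null alternative
keeps the same divergence but a single constant ancestral size; its
prior is not part of any published table and defaults to U[10³, 5×10⁶],
mirroring the ancestral-size prior.

A finite-island variant (within-deme coalescence `1/(2N)`, per-lineage
migration at rate `m` to a uniformly chosen other deme) provides the
neutral null for the outlier scan. For this exact model the expected FST
has the closed form `1/(1 + 4Nm·d/(d−1))`, derived from the pairwise
coalescence times `T_within = 2Nd` and
`T_between = 2Nd + (d−1)/(2m)`; the simulator is tested against it and
against the `E[T_pair] = 2N` single-deme expectation. (The often-quoted
`(d/(d−1))²` factor belongs to a different forward-time migration
convention and does not match this model; simulation confirms the
single-factor form.)

### A note on the bottleneck's direction of effect

For *ascertained single-mutation SNPs*, tightening the refugium
bottleneck **raises** the gene diversity of surviving loci: a strong
bottleneck coalesces most lineages quickly, so the tree is dominated by
a few deep, long branches, mutations land on them, and derived alleles
sit at intermediate frequencies. (For unascertained sequence diversity
the familiar direction — bottlenecks erode diversity — holds; the
reversal is a property of the SNP ascertainment scheme.) The ABC relies
only on this monotone, systematic shift, and the test suite checks the
empirically correct direction.

## Approximate Bayesian computation

The summary layer is the six-statistic family used by DIYABC-style SNP
analyses, eight numbers for two samples: per sample, mean gene diversity
across polymorphic loci and across all loci; per pair, mean per-locus
Weir–Cockerham FST and mean Nei (1972) standard distance
$D = -\ln(J_{xy}/\sqrt{J_x J_y})$, each over "nonnull" loci (defined and
nonzero — one of two possible readings of nonnull, exposed as the
implemented convention) and over all loci with undefined values counted
as zero. Note that for biallelic loci fixed for opposite alleles,
$J_{xy} = 0$ makes Nei's D infinite; such loci fall out of the nonnull
mean and count as zero in the all-loci mean.

Rejection standardizes each statistic by its standard deviation across
the reference table (a scale normalization comparable to DIYABC's;
zero-variance statistics are excluded with a warning), retains the
closest `tolerance` fraction by Euclidean distance (default 1%,
matching the ten-thousand-of-10⁶ convention), and model choice offers
both the direct estimate (scenario frequencies among retained rows) and
multinomial logistic regression of the scenario label on the
standardized statistics evaluated at the observed point. Two
implementation details stabilize the logistic step on small retained
sets: statistics that are duplicated to numerical precision (|r| >
0.999 — on ascertained simulated data the polymorphic-loci and all-loci
diversity means coincide) are dropped, and retained rows are weighted by
the Epanechnikov kernel on rejection distance, mirroring the
local-linear step.

Parameter estimation is Beaumont-style local-linear adjustment: sizes are
log-transformed, times logit-transformed against their prior bounds (so
adjusted draws always respect the prior support), each transformed
parameter is regressed on the standardized statistics with Epanechnikov
weights, and the fit at the observed point replaces the fitted part.
Posterior modes come from a weighted Gaussian kernel density (Silverman
bandwidth) on the untransformed scale; intervals are weighted 5%/95%
quantiles. Aliased regression columns are treated as zero-coefficient
(the pivoted least-squares fit); a genuinely singular fit falls back to
the unadjusted rejection sample with a warning.

Scenario confidence simulates pseudo-observed datasets (PODs) under each
scenario, classifies each against the full reference table, and reports
the type I error (focal-scenario PODs not assigned to the focal
scenario) and type II error (alternative PODs assigned to the focal).

### What desk-scale ABC can and cannot reproduce

The published analysis used 10⁶ simulations per scenario and PODs drawn
from the data-fitted joint posterior, and reported type I/II errors of
0.04/0.05 and a posterior probability of 1 for the two-decline history.
At the package's desk scale (5,000 simulations per scenario, 1,000-locus
datasets, PODs drawn *independently uniformly* over the published
posterior 5–95% ranges), the two scenarios' summary-statistic
distributions overlap much more: a random forest trained on the full
reference table misclassifies about half of it, which bounds what any
procedure — including rejection plus logistic regression — can achieve
under these conditions. The corresponding acceptance checks are
therefore expected to report substantially larger errors than the
published ones; the package computes them honestly rather than
recalibrating the setup, and the parameter-recovery check (posterior
intervals covering the generating refugium size and European-decline
time) is the desk-scale property that *is* reproducible. The
model-choice probability for a single posterior-mode dataset is itself
noisy at 1,000 loci (its mean diversity has a standard error near
0.005, which spans the contested region between the scenarios), so that
check varies from run to run.

## Outlier scan

The FDIST-style scan computes per-locus multi-population θ and pooled
heterozygosity, calibrates an island-model null to the trimmed mean of
the observed θ (25% trim; a single calibration pass plus an optional
simulated refinement), simulates the null at matched sample sizes, bins
simulated (He, θ) pairs by He (width 0.02, empty bins merged with the
nearest occupied bin), and assigns each observed locus a two-sided
rank-based tail probability within its bin, with (k+1)/(n+1) smoothing.
Benjamini–Hochberg q-values correct for multiple testing; loci with
q ≤ FDR are partitioned into diversifying and balancing tails, and the
per-bin envelope at the requested confidence level (default 0.99) is
reported for plotting.

Because the p-values are rank-based with finite simulation tables, they
have a resolution floor of 2/(B+1) for a bin with B simulations; with
realistic table sizes this makes single-locus discoveries at stringent
FDR thresholds conservative. More consequentially, a single locus
simulated at, say, five times the null divergence carries large
*genealogical* variance — its realized θ frequently falls inside the
null envelope no matter how many individuals are sampled — so per-locus
power against moderate selection is intrinsically limited (roughly 60%
at the 0.99 envelope in the regimes exercised here, and lower after FDR
correction). The scan's calibration (null data produce approximately
uniform p-values and essentially no calls at FDR 0.05) is the property
that holds robustly; near-fixed loci are detected reliably.

## Assignment

Leave-one-out home-likelihood assignment scores every individual against
every colony (or cluster): the home colony's allele frequencies are
recomputed without the focal individual; frequencies of exactly 0 or 1
are replaced by 0.005 and 0.995 without renormalization (the cited
program's documented convention; the perturbation is negligible at SNP
scale); genotype likelihoods assume Hardy–Weinberg proportions and sum
log10 probabilities over loci. Missing calls are imputed once per
analysis by drawing allele pairs from the global pool, seeded. The home
p-value compares the observed home likelihood with 10,000 genotypes
simulated from the home leave-one-out frequencies ("number of datasets"
in the cited program's terms); assignment accuracy is the fraction of
individuals whose argmax population is their sampling population —
the p-value is reported separately and does not gate correctness.
Cluster-level assignment pools individuals by cluster and recomputes
frequencies rather than summing colony likelihoods.

## The synthetic-study generator

The generator emulates the study design, not any particular dataset:
eight colonies with the published sample sizes (167 pups), three
clusters, and an admixture zone. Per locus, an ancestral alternate-allele
frequency is uniform on [0.03, 0.30] (randomly flipped to keep minor
allele orientation arbitrary); this window implies a mean expected
heterozygosity of 0.263, the observed regime. Cluster frequency pools are
Balding–Nichols draws around the ancestral frequency with drift
`f_cluster = 0.015`; colonies drift `f_colony = 0.003` around their pool;
the admixture-zone colonies draw from a weighted mixture of the two main
pools (weights 0.6 and 0.5). These defaults put within-cluster pairwise
θ near 0.003–0.006 and between-cluster θ near 0.018 — the published
0.003–0.022 range — and give the Mantel test a weak but real
isolation-by-distance signal because the clusters are geographically
segregated. Missing calls are masked completely at random at rate 0.02.

What the generator does *not* emulate: genotyping-by-sequencing artefacts
(depth-dependent dropout, paralogous stacks), within-colony kin
structure, linkage, or ascertainment bias of the real SNP panel. Passing
tests on synthetic data therefore demonstrate correctness of the
estimators and pipeline plumbing under the intended population model,
not robustness to GBS noise.

## Problem sizes used by the checks

The packaged checks run at sizes chosen to exercise the methods
meaningfully on one core: reference tables of 5,000 simulations per
scenario with 1,000-locus datasets and samples of 101 and 66 diploids
for model choice; 20,000 simulations for parameter recovery (tolerance
1%, 20 replicate datasets); 500 PODs per scenario for the error rates;
island-model null tables of 30,000–300,000 single-locus simulations for
the outlier checks; and synthetic studies of a few hundred to a few
thousand loci elsewhere. The full published scale (10⁶ simulations,
26,026 SNPs) is configuration-reachable through the same functions.

## Known limitations

- The ABC summary layer is the eight-statistic mean family; statistics
  beyond means (e.g. across-locus variances) are not implemented, which
  limits scenario separation at small reference-table sizes.
- The null-scenario constant-size prior is a package default
  (U[10³, 5×10⁶]), not a published value.
- PED/MAP files do not name reference alleles; the reader designates the
  lexicographically smaller observed allele as reference, so a locus
  monomorphic in a file cannot round-trip its allele identity.
- The LD filter is window-based; PLINK's exact `--indep` variants are
  not reproduced parameter-for-parameter.
- Assignment treats loci as independent (no LD-aware likelihood).
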