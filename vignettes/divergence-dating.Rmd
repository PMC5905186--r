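---
title: "Dating a recent population split from joint SNP class frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a recent population split from joint SNP class frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(snpclock)
```

## The problem

When an ancestral population splits into a large "source" population and a
small, recently founded one (the motivating system is the Pachon cave
population of *Astyanax mexicanus* against a Texas surface population),
shared ancestral polymorphism persists for a while, is progressively sorted
by drift, and is replenished by migration. The joint configuration of each
SNP across the two populations -- who is polymorphic, who is fixed, and for
which allele relative to an outgroup-polarized ancestral state -- therefore
carries a clock: young splits are dominated by shared polymorphism, old
splits by divergently fixed alleles. `snpclock` turns that signal into an
age estimate by forward simulation.

Two properties make the approach attractive for pooled sequencing data.
First, the summary statistics are *relative class frequencies*, which do not
depend on the mutation rate (a higher input of mutations scales every class
count equally), so the age estimate depends only on the demographic
parameters and the generation times. Second, classification only needs
population allele frequencies, which is exactly what Pool-seq provides.

## The eight SNP classes

With an outgroup identifying the ancestral allele (`polarize()`), every
biallelic site falls into one of eight joint patterns
(`classify_site()`): classes 1 and 2 are divergent fixations (derived allele
fixed in the cave or in the surface population, respectively), classes 3-6
are private polymorphisms subdivided by which allele the other population
has fixed, class 7 is shared polymorphism, and class 8 ("divergent
polymorphism", different allele pairs segregating in the two populations)
requires two independent mutations at the same site and is essentially a
sequencing-error alarm: it is structurally empty under the infinite-sites
simulation and nearly empty in real data.

A population is called polymorphic when its minor allele frequency exceeds
`maf_min` (default 5%), otherwise it is treated as fixed for its major
allele. Treating sub-threshold minor alleles as absent mirrors the
polymorphism-calling filter applied to the data, and matters: pooled
frequencies are noisy and the laboratory observation model below makes rare
alleles unobservable anyway.

```{r}
s <- class_summary(observed_snp_classes()[, "synonymous"])
s
```

The packaged `observed_snp_classes()` matrix is the published
surface-vs-cave classification at synonymous, non-coding and non-synonymous
sites. Its two headline asymmetries -- roughly 3 times more polymorphism in
the surface population, yet roughly 2.3 times more fixed derived alleles in
the cave population -- are the signature of a recent split with strong drift
in the small population: fixation probability of a neutral allele is its
frequency in both populations, but the *time* to fixation,
$\bar t_1(p) = -4N\frac{1-p}{p}\ln(1-p)$ generations
(`expected_fixation_time()`), scales with $N$, so the small population
transiently fixes ancestral variants faster. That excess vanishes at
equilibrium, which is why it is informative about the age.

## Site filtering

`apply_filters()` retains a site iff pooled depth is at least 100 in each
population, the contig annotation e-value is below $10^{-5}$, no other SNP
lies within 50 bp on either side (computed among depth/e-value-passing
sites, since clusters of spurious calls should be removed regardless of
their own quality), and the site is still a SNP after sub-threshold minor
alleles are called fixed. Discards are attributed to the first failing rule
in that order. The depth rule is inclusive (`>= 100`); the other three are
strict, as in the thresholds above. Filtering is idempotent.

## The forward simulator

`wf_run_split()` implements an isolation-with-migration model on a one-year
integer clock, which is what allows the two populations to have different
generation times (2 years for surface fish, 5 years for cavefish -- the age
in years is the product of generations and generation time, so these two
numbers propagate linearly into the estimate):

* The ancestral population (diploid size `n_anc`) sits at mutation/drift
  equilibrium. Each generation, a population of size $N$ receives a
  Poisson($2Nu$) number of new loci at frequency $1/2N$; with the default
  $u = 0.02$ per haploid genome per generation, the surface population gains
  on average 400 new SNPs per generation at frequency $5\times10^{-5}$, the
  cave population 50 at $4\times10^{-4}$. $u$ only sets the Monte-Carlo
  resolution of the class frequencies (more loci, smoother frequencies),
  not their expectation.
* At the split both daughters inherit the ancestral frequency vector and
  change size instantaneously; thereafter each locus drifts binomially,
  independently, with no selection or linkage.
* Migration is surface-to-cave only (cave-to-surface migration is taken as
  negligible): each year, with probability `mig_prob_per_year`, a pulse
  deterministically replaces a fraction `mig_frac` of the cave gene pool,
  and drift at the next cave reproduction supplies the sampling noise. The
  pulse law separates "few migrants often" from "many migrants rarely".
* Loci lost in both populations are pruned; loci fixed in both are pruned
  and counted as shared substitutions. Divergently fixed loci stay tracked
  (migration can re-mobilize them, and they populate classes 1 and 2).
* Every `checkpoint_years` (100 years = 50 surface = 20 cave generations),
  both populations are *virtually* observed through the lab model: 10
  diploids are sampled binomially, then drift 10 generations at $N_e = 10$
  with no mutation (`wf_lab_sample()`). With 20 sampled alleles and the 5%
  MAF rule, singletons count as fixed. The lab bottleneck is a large part
  of the observation noise and is deliberately part of the model, since the
  real data came from lab stocks.

### Burn-in

The ancestral equilibrium is initialized from the analytic neutral
infinite-sites spectrum -- a Poisson($4N u/i$) number of loci at each derived
count $i$ -- followed by 1000 Wright-Fisher settling generations
(`wf_burn_in()`). Initializing at the stationary law and settling briefly
gives the same distribution as the from-scratch alternative
(`init = "empty"`, $10N$ generations from no variation, kept for
cross-checking) at a small fraction of its cost; the two are compared in the
test suite at small $N$, where both match the closed-form segregating-site
count $4Nu\sum_{i=1}^{2N-1} 1/i$.

## Scoring and the age estimate

`fit_divergence_age()` scores every checkpoint age with a chi-square-type
distance between simulated and observed 7-class frequency vectors
(class 8 is excluded as empty),
$\sum_c (f^{sim}_c - f^{obs}_c)^2 / \max(f^{obs}_c, \varepsilon)$,
and returns the age minimizing it (ties resolve to the youngest age -- the
conservative direction). The distance lives behind `gof_score()` so that
alternatives (Euclidean, Hellinger) can be swapped; the argmin age is robust
to any sensible choice, while the absolute score value is not comparable
across choices and is therefore never interpreted.

```{r, fig.width = 6, fig.height = 4}
obs <- class_summary(observed_snp_classes()[, "synonymous"])
p <- demographic_params(n_anc = 1000, n_sf = 1000, n_cf = 125,
                        max_years = 6000)
fit <- fit_divergence_age(obs, p, seed = 1)
summary(fit)
plot(fit, which = 1)
```

(The chunk above runs a reduced-scale model so the vignette builds in
seconds; the full configuration -- ancestral and surface size 10,000, cave
size 1250, migration pulses at 0.001/yr replacing 1% of the cave pool,
horizon 50,000 years -- is what `scripts/acceptance.R` runs, in about half a
minute per replicate.) The score profile is U-shaped: young ages retain too
much shared polymorphism, old ages too little and too many cave fixations.
Because the basin around the minimum is shallow and the simulation is
stochastic, the argmin varies by one or two thousand years between seeds;
replicate with `simulate(fit, nsim = ...)` when that matters.

`sweep_divergence_fits()` repeats the fit over a parameter grid (ancestral
size, cave size, migration law, ...) with pre-drawn per-point seeds, which
is how the qualitative screens are reproduced: no fit exists when the cave
population is as large as the surface one, and good fits concentrate at
small cave sizes and recent ages. A reported alternative configuration
(cave size 625 with 0.1% migrant pulses) behaves similarly to the default
(1250 with 1%); the defaults here follow the configuration whose age
trajectory is analysed in detail.

## Synthetic data

`make_site_table()` draws class labels multinomially and materializes a
site table with consistent counts, depths, e-values and positions, plus
controlled fractions of filter violations, so the classification and
filtering path is testable without any sequencing input. Within a
polymorphic population the minor allele frequency is drawn uniformly on
(`maf_min`, 0.5] -- the within-class frequency does not enter any downstream
statistic, only class membership does. `make_truth_observed()` generates
"observed" summary statistics from the simulator itself at a known age for
parameter-recovery tests, and `make_quartet()` builds four-taxon alignments
whose informative sites all support a chosen topology.

What the generators deliberately do not emulate: read-level sequencing
error, reference bias, linkage between nearby SNPs within a contig, and
selection. Passing tests on synthetic tables therefore validate the
bookkeeping and the neutral-drift machinery, not the biological adequacy of
the neutral IM model for any particular dataset.

## Quartet incongruence

`topology_support()` counts parsimony-informative sites (`xxyy` columns;
gaps and ambiguity codes exclude a column, following standard parsimony
practice) for the three unrooted topologies of a four-taxon alignment and
reports the winning split as taxon-id partitions, so input order is
immaterial. Genes that individually support different topologies with
internally consistent sites (`is_congruent()`) are the expected signature of
incomplete lineage sorting among recently separated populations -- the same
phenomenon, seen from the tree side, that the dating model exploits from
the frequency side.

## Numerical choices and limitations

* Problem sizes in the test suite are reduced (ancestral/surface size 1000,
  cave size 125, horizons of a few thousand years) so the whole suite runs
  in minutes; the acceptance script runs the full configuration.
* Checkpoint ages are the only candidate ages: the estimate's resolution is
  `checkpoint_years` (100 years by default).
* Lab samples are re-drawn independently at every checkpoint; the virtual
  sampling never perturbs the wild populations.
* `demographic_params()` enforces that the checkpoint interval is a common
  multiple of both generation times, so every checkpoint sees both
  populations immediately after a reproduction.
* All randomness flows through R's global RNG; every user-facing entry
  point takes a `seed` argument and is bit-reproducible given it.
* The estimator inherits the model's assumptions: neutrality of the scored
  sites (use synonymous classes), free recombination between loci, a single
  clean split, one-way migration, and known generation times. The age
  scales linearly with the assumed cave generation time, which is the
  single largest systematic uncertainty.
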