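---
title: "Genomic dimensionality, GWAS sample size, and single-step prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic dimensionality, GWAS sample size, and single-step prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In livestock populations the genomic information carried by any number of
genotyped animals is finite: chromosome segments are inherited in blocks
whose expected count is `Me = 4 Ne L`, with `Ne` the effective population
size and `L` the genome length in Morgans. The number of largest eigenvalues
of the genomic relationship matrix **G** explaining *x*% of its variance
(EIG*x*) measures this dimensionality empirically — EIG90, EIG95 and EIG98
track `NeL`, `2NeL` and `4NeL`. `eigdim` implements a full simulation
pipeline to study two practical consequences:

1. how large a genome-wide association (GWA) discovery set has to be before
   causal variants (QTN) become detectable, as a function of `Ne`, trait
   heritability, and polygenicity; and
2. how much single-step GBLUP (ssGBLUP) prediction accuracy improves when
   GWA-preselected variants are added to a regular 50k SNP chip.

## Pipeline and models

**Simulation (`simulate_population`).** A historical phase (random union of
gametes, recurrent allele-flip mutation at 2.5e-5, population size following
anchor points with linear interpolation — the full design expands 1000 to
50,000 and contracts to 20,000 over 2000 generations) builds linkage
disequilibrium and mutation–drift equilibrium from founders at allele
frequency 0.5. A recent phase mates a small number of sires (5 or 50, which
sets `Ne` near 20 or 200 in the full design) to 15,000 dams for 20
generations, one offspring per dam; 80% of sires and 30% of dams are
replaced each generation by random offspring, culling the oldest breeders
first with random tie-breaking. Meiosis is Haldane: Poisson crossover
counts per chromosome length, uniform breakpoints, no interference,
independent assortment. Loci with minor allele frequency strictly above
0.05 in the recent founder cohort are retained and labelled SNP or QTN.
QTN effects are gamma(0.4) magnitudes with random signs, rescaled by one
constant so the founder-cohort variance of true breeding values (TBV)
equals the target additive variance `sigma_u2 = h2` (phenotypic variance is
1). Phenotypes are `1.0 + TBV + N(0, 1 - sigma_u2)` for the last ten
generations; the last five generations are genotyped.

**Dimensionality (`eigen_profile`, `n_eigen_for_pct`).** The EIGx machinery
operates on the SNP-only (QTN-excluded) VanRaden **G** over all genotyped
animals. Eigenvalues are sorted descending, small negatives (within
`1e-8 x trace`) are clipped, and EIGx is the smallest `k` whose cumulative
eigenvalue fraction reaches `x/100`. Discovery/training sets of size EIGx
are drawn nested (each level contains the previous) from two disjoint
pools after reserving the last genotyped generation as the test set.

**GWA (`reml_null`, `assoc_scan`).** The mixed model is
`y = 1 mu + x_i b_i + u + e` with `u ~ N(0, G sigma_u2)` and the scan GRM
built as the mean-centered cross-product averaged over loci. Following the
EMMAX approximation, the null variance components are estimated once by
REML — a single spectral decomposition of **G** plus a 1-D profile
likelihood over the ratio `delta = sigma_e2/sigma_u2` (optimized on
`log10 delta` in [-6, 6]) — and held fixed during the per-variant
generalized least squares scan. Each variant is tested by a two-sided Wald
t-test with `n - 2` degrees of freedom; with an identity covariance this
reduces exactly to simple-regression p-values, which is one of the test
oracles (the other is a dense per-variant GLS with the full covariance
inverted). Significance uses Bonferroni: `0.05 / (number of SNPs + QTN
scanned)`. A QTN counts as identified only when the QTN variant itself
passes the threshold; the variance it explains is `2 p q beta^2 / sigma_u2`
with the true simulated effect and the discovery-cohort frequency, and
scenario totals sum this over identified QTN. The sample size needed to
reach a target variance-explained level is read off a loess fit
(span 0.75, degree 2) of the level against sample size, inverted by linear
interpolation on a 512-point grid.

**Prediction (`run_prediction_scenario`).** ssGBLUP solves
`y = 1 mu + Z u + e` with `u ~ N(0, H sigma_u2)` where
`Hinv = Ainv + [0 0; 0 Ginv - A22inv]` over the evaluation pedigree (the
phenotyped generations; parents outside it become unknown base animals).
**A** is Wright's numerator relationship matrix by the tabular method with
inbreeding; **G** is VanRaden method 1 on the requested marker panel over
the training and test animals, centered at training-cohort frequencies and
blended as `0.95 G + 0.05 A22` before inversion. Only training phenotypes
enter `y`; variances are the simulated ones, not re-estimated. PBLUP runs
the same equations with `Ainv`. Chip panels take every tenth SNP in genome
order starting at the first (the phase is unstated in the source design;
systematic-from-first is the convention adopted); augmented panels add the
`v` smallest-p variants (TOPv, ties broken by genome position) or all
Bonferroni-significant variants (SIG), deduplicated against the chip.
Validation on the untouched last-generation test set reports accuracy
(`cor(TBV, GEBV)`) and dispersion (`b1 = cov(TBV, GEBV)/var(GEBV)`; below
1 signals inflation).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_sires` | 50 | breeding males per generation; the Ne control (5 -> Ne ~ 20, 50 -> Ne ~ 200 in the full design) |
| `n_qtn` | 200 | causal loci (200 = less polygenic, 2000 = more polygenic) |
| `h2` | 0.3 | heritability = additive variance (varP = 1); proxies the reliability of the records (0.3, 0.9, 0.99) |
| `maf_min` | 0.05 | strict MAF filter applied in the recent founder cohort |
| `mutation_rate` | 2.5e-5 | recurrent allele-flip probability per locus per meiosis |
| `gamma_shape` | 0.4 | QTN effect-size distribution shape |
| blending weight | 0.05 | share of A22 mixed into G before inversion |
| scan `alpha` | 0.05 | family-wise error rate before Bonferroni division |
| loess span / degree | 0.75 / 2 | sample-size inversion smoother |

## What the generator emulates — and what it does not

The synthetic data reproduce the design counts of the full-scale study
exactly (315,005 / 315,050 recent animals for 5 / 50 sires, 75,000
genotyped, 15,000 test, 30,000-strong discovery and training pools) and its
stochastic structure qualitatively: drift follows Wright–Fisher
(heterozygosity decay `(1 - 1/(2N))^t` is a test oracle), recombination
follows Haldane's map function, and the EIGx counts order with `Ne` as
`Me = 4NeL` predicts. It does not emulate real genomes: no variable
recombination rate, no selection, migration or overlapping generations, no
genotyping error, and a genome far smaller than 29 chromosomes at test
scale. A green suite therefore establishes that the machinery is correct
and that the qualitative orderings hold in a small stated world — not that
the published full-scale numbers are reproduced; those require cluster
time with `sim_config()` defaults.

## Numerical choices

- REML: the profile optimum is compared against the interval endpoints to
  guard against flat profiles; estimates at the bounds are flagged
  `boundary`, a zero-variance phenotype short-circuits to a `degenerate`
  fit.
- Scan: variants whose rotated residual sum of squares is within `1e-12`
  of zero (monomorphic) are reported with `beta = 0, p = 1` and flagged.
- Eigenvalues below `1e-8 x trace` in magnitude are clipped to zero;
  larger negatives raise an error rather than being silently absorbed.
- Positions are continuous Morgans; duplicated map positions are broken
  deterministically by (class, locus id) with a warning.
- The historical size trajectory interpolates linearly between schedule
  anchors, which is all the source design states.
- Child seeds derive from the master seed by a documented multiplicative
  counter (`derive_seed`), so any scenario/replicate can be re-run in
  isolation; all values stay below 2^31.

## Open design points resolved here

- One offspring per dam per generation (the only litter size consistent
  with the 315,005 / 315,050 totals).
- MAF filtering happens in the recent founder cohort, not the historical
  generation 0.
- TOPv/SIG augmentation is a union-with-dedup against the chip; TOPv may
  select QTN and SNPs alike.
- The EIGx count from the all-genotyped-animals GRM is used for both the
  discovery and training set sizes (a single set of numbers, as published).
- Discovery and training sets are disjoint by default, which showed less
  GEBV inflation; `scheme = "same"` reproduces the alternative.
- Evaluation pedigree depth is the phenotyped generations (11–20 at full
  scale); unphenotyped relatives there enter the pedigree but not `y`.
- MME variances are the simulated, scenario-specific values.

## A worked desk-scale example

```{r, eval = FALSE}
library(eigdim)
cfg <- sim_config(n_chromosomes = 2, genome_length = 2, n_snp = 1500,
                  n_qtn = 60,
                  hist_schedule = data.frame(generation = c(-150, -80, 0),
                                             size = c(80, 400, 200)),
                  n_sires = 8, n_dams = 120, n_generations = 20,
                  genotyped_generations = 16:20, pheno_generations = 11:20,
                  h2 = 0.9)
tbl <- run_scenario_replicate(cfg, x_levels = c(50, 90, 98), seed = 3)
tbl[, c("level", "n_set", "model", "panel", "accuracy", "b1")]
```

On this seed the training-set gradient is visible directly: ssGBLUP
accuracy on the chip panel rises from 0.32 (EIG50, 15 animals) through
0.55 (EIG90, 82) and 0.78 (EIG98, 191) to 0.79 with the whole 240-animal
pool, while PBLUP stays at 0.50 with the full pool — the ssGBLUP-over-PBLUP
and more-data-helps orderings of the full-scale study, at desk size.

## Known limitations

- The EMMAX approximation shares one null variance fit across variants;
  strong single-variant effects are mildly conservative compared with a
  per-variant REML (exact GLS agreement is enforced only at the fixed
  components).
- Dense linear algebra throughout: pedigrees beyond ~10k animals or
  genotype sets beyond ~20k x 500k need the full-scale (cluster)
  configuration and out-of-core tooling that this package deliberately
  does not ship.
- At desk scale the EIG98 count of a large-Ne population can exceed the
  half-pool size, so nested EIG98 selection sets are infeasible there (the
  constructor raises the documented pool error); pattern grids use levels
  that fit, and the EIG98 Ne-ordering is checked on eigen counts directly.
- Two full-scale orderings do not transfer to desk scale and their
  acceptance checks are intentionally left failing rather than weakened.
  With a ~2-Morgan genome and a 300-animal pool, the large-Ne population's
  `Me = 4NeL` (~1200) exceeds the discovery pool several-fold, a sampling
  regime the full design never enters (its pools are 1.6–16x Me); there
  the large-Ne advantage in variance explained at matched sample size can
  invert (observed at h² = 0.99), and near-zero-power cells (h² = 0.3,
  large Ne) leave the monotone-in-sample-size ordering of replicate means
  vulnerable to single-hit noise. Reproducing the published regime needs
  pools of thousands of genotyped animals — cluster-scale configuration.
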