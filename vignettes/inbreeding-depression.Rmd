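---
title: "Mapping inbreeding depression from runs of homozygosity"
author: "rohdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping inbreeding depression from runs of homozygosity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohdep)
```

## The problem

Mating between relatives raises genome-wide homozygosity and depresses
quantitative traits — inbreeding depression. In dairy cattle the male side
of fertility is economically important (one artificial-insemination bull
serves thousands of cows) yet rarely analysed: semen traits such as
ejaculate volume (EV, mL), sperm concentration (SC, 1e8 per mL) and sperm
motility (SM, proportion of forward-moving sperm) are recorded repeatedly
per bull at AI centres. `rohdep` implements, end to end, a genomic
analysis of inbreeding depression for this kind of data:

1. genomic inbreeding coefficients from SNP arrays — excess homozygosity
   (`F_SNP`) and runs of homozygosity (`F_ROH`, plus ROH length classes
   that separate recent from ancient inbreeding);
2. a repeated-records animal model regressing phenotypes on inbreeding,
   fitted by AI-REML with a genomic relationship matrix and a
   permanent-environment term;
3. a per-SNP association scan of the *ROH state* of each marker, with a
   proportion-based false-discovery rate and region calling;
4. a gene-dropping simulator with exactly tracked identity-by-descent
   (IBD), so that every stage can be validated against known truth.

## Runs of homozygosity

A run of homozygosity is a contiguous stretch of homozygous genotypes,
used as a proxy for autozygosity. A SNP interval qualifies when it
satisfies all of (defaults in `rohParams()`):

* span at least 1 Mb (1-based, closed interval from first to last SNP);
* at least 15 SNPs;
* average density of at most 1 SNP per 100 kb (`span / n_snps <= 1e5`);
* at most one heterozygous call;
* no gap between adjacent SNPs larger than 500 kb.

`detectRoh()` uses no sliding-window heuristic. It enumerates, per
individual and chromosome, every *containment-maximal* interval
satisfying the constraints (an exact frontier search over the density
condition, checked against an O(n^2) brute-force oracle in the test
suite), and then reports the non-overlapping subset grown greedily from
the left. The greedy step matters: around an absorbed heterozygote two
maximal intervals overlap (one absorbing it from each side), and
reporting both would double-count bp — early development showed this
inflating `F_ROH` by ~50% for highly inbred animals. One consequence,
documented here deliberately: because threshold changes can re-select
which maximal interval is reported around a heterozygote or where the
density cap binds, coverage is guaranteed to grow under relaxed
length/SNP-count thresholds only when the heterozygote allowance is 0 and
the density cap is inactive; the property test pins exactly that regime.

Segment lengths are decomposed into the classes [1,2), [2,4), [4,8),
[8,16), [16,Inf) Mb (lower-closed bins). The expected length of an IBD
haplotype whose common ancestor lived `g` generations ago is `100/(2g)`
Mb (`expectedIbdLength()`), so the classes read as an age spectrum:
1–2 Mb runs trace back roughly 50–25 generations, segments beyond 16 Mb
to the last ~3 generations.

## Inbreeding coefficients

For sample `i` over `s` SNPs with minor allele frequencies `m_j`
(computed from the analysed sample itself; no external frequency source):

* `F_SNP_i = (OH_i - EH) / (s - EH)` with `OH_i` the observed count of
  homozygous genotypes and `EH = sum_j [1 - 2 m_j (1 - m_j)]`. It is 1
  for a fully homozygous genome and negative when homozygosity falls
  below Hardy–Weinberg expectation.
* `F_ROH_i = sum_k L_ROH_ik / L_g`, the fraction of the SNP-covered
  autosomal genome (`L_g`, summed closed spans per chromosome) lying in
  called ROH; class-specific `F` values use the same denominator and sum
  exactly to `F_ROH`.

Following standard practice, `F_SNP` and ROH calling use the *full*
marker set, including low-MAF markers, whereas the genomic relationship
matrix is built from the post-QC set (MAF >= 0.01, Hardy–Weinberg
chi-square p >= 1e-6; `filterMarkersQC()`). The HWE test is the Pearson
1-df chi-square without continuity correction — the conventional
array-QC choice, matching the default chi-square mode of the standard
command-line tooling.

## The animal model

With repeated records `y_ijklm` on bull `m`:

```
y = mu + year_season + AI_centre + interval + n_sample
      + b1 * age + b2 * F_m + animal_m + perm_m + e
```

`animal ~ N(0, G sigma_a2)` with `G` the VanRaden method-1 genomic
relationship matrix (`Z Z' / (2 sum p q)`, observed frequencies, 1e-6
diagonal ridge), `perm ~ N(0, I sigma_pe2)` capturing non-genetic
covariance among a bull's records, and `e ~ N(0, I sigma_e2)`.
Model 1 uses one inbreeding covariate (`F_ROH` or `F_SNP`); model 2 fits
the five ROH length-class coefficients simultaneously (they are
correlated, so joint fitting is essential); the base model (no `F`) gives
heritability `h2 = sigma_a2 / (sigma_a2 + sigma_pe2 + sigma_e2)` and
repeatability `(sigma_a2 + sigma_pe2)` over the same total, conventionally
reported from the fit that excludes the inbreeding effect.

`fitAnimalModel()` estimates the variance components by
average-information REML. Numerics worth knowing:

* All per-iteration algebra is reduced to bull-level (q x q) matrices via
  the Woodbury identity, so a fit with thousands of records takes well
  under a second.
* AI steps that leave the parameter space or would decrease the
  restricted likelihood are step-halved; if that fails an EM step is
  taken, so the accepted log-likelihood trajectory (kept in the
  `FitResult`) is non-decreasing. Components pinned at the lower bound
  (1e-10 of the phenotypic variance) with a downhill score are frozen out
  of the AI system — without this, boundary cases crawl.
* Convergence: relative VC change < 1e-8 or log-likelihood change
  < 1e-9, at most 200 iterations; non-convergence is an error that
  carries the trajectory.
* Starting values default to equal thirds of the phenotypic variance;
  informative priors can be supplied.
* Fixed-effect inference: `t = estimate / SE` with `n_bulls - rank(X)`
  degrees of freedom — the bull count, not the record count, is the
  effective replication for per-bull covariates such as `F`. Aliased
  columns are reported as `NA` rows, never dropped silently.

## The per-SNP scan and FDR

Model 3 replaces `F` with two covariates of the focal SNP: its additive
dosage (0/1/2) and its 0/1 *ROH state* (1 when the SNP lies inside a
called ROH of that bull). The ROH-state coefficient measures the effect
of local homozygosity after removing the additive allele effect — the
inbreeding-depression signal at that position.

`runScan()` holds the variance components fixed at the base-model REML
estimates and solves each SNP's GLS by rank-two updates of precomputed
bull-level projections, so the 52k-SNP scan of the real design is a few
seconds. A property test verifies exact agreement (to 1e-8) with a dense
joint GLS refit. SNPs whose ROH state never varies (or is collinear with
their own dosage) get `status = "NA_no_variation"`.

Multiple testing uses the proportion-based estimate
`FDR = P (1 - N) / (N (1 - P))` where `P` is the p-value threshold and
`N` the observed proportion of tested SNPs below it;
`minFdrThreshold()` scans candidate thresholds for the minimum.
`callRegions()` merges significant SNPs within 1 Mb (the merge gap is a
flag — published region lists rarely state their clustering rule) and
looks up genes within 500 kb on either side.

## What the simulator emulates — and what it does not

`simulateGenotypes()` drops gametes through an explicit pedigree:
founder haplotypes drawn per SNP from `founderMafRange`, Haldane
recombination at 1 cM/Mb, a burn-in of random mating at a modest
population size (ancient, short IBD), and a final generation in which a
fraction of bulls come from full-sib matings (recent, long IBD; expected
IBD fraction 0.25). IBD is defined by founder-haplotype identity — not
allele identity — which is exactly the distinction ROH methods are meant
to capture, and the truth object records per-bull IBD fractions, segment
lists and the SNP-level IBD state used to inject locus-specific effects.

Default scenario (chosen once; all tests use it or scaled-down variants):
300 bulls, 5 chromosomes x 100 Mb at 50 kb spacing (10,000 SNPs), 150
founders, 5 burn-in generations, 30% full-sib matings, 6–30 records per
bull, variance components (2.3, 4.5, 14.4) giving h2 ~ 0.11 and
repeatability ~ 0.32 on an SC-like trait (mean 12.67), age slope 0.02 per
month, and a genome-wide depression slope of -5 trait units per unit
IBD. The founder diversity and mating design were calibrated so the
called mean `F_ROH` (~0.09) matches what Holstein bull panels typically
show; with these settings the called `F_ROH` tracks the true IBD
fraction almost perfectly, which is what makes slope-recovery checks
meaningful.

Features of real data deliberately *not* emulated: coalescent-accurate
linkage disequilibrium, ascertainment of array SNPs, genotyping error
and missingness (the methods assume imputed data), selection and purging
dynamics, and the deep pedigree behind real ROH length spectra (the
burn-in is a stand-in). The truth's "generation of origin" for an IBD
segment is a length-based estimate (`100/(2L)`), since founder-haplotype
labels carry no coalescent times. Passing tests therefore demonstrate
the correctness and calibration of the *methods* under a controlled
generative model, not the biology of any particular population.

A note on test design: p-values of neighbouring SNPs in the scan share
ROH segments and are strongly correlated, so the type-I-error check
pools approximately independent draws (one tested SNP per chromosome per
replicate across seeded null replicates) before applying a binomial
bound; applying it to all SNPs of one scan would test an independence
assumption the data structure plainly violates.

## Degenerate inputs and tie-breaks

* Monomorphic-only marker sets: QC returns an empty set (not an error);
  `F_SNP` is undefined (`s == EH`) and errors with a message.
* A chromosome with fewer than two SNPs is excluded from `L_g` with a
  warning; an empty map is an error.
* Phenotype range filters are closed intervals (EV [1, 25] mL,
  SC [1, 30] 1e8/mL, SM [0.1, 0.98]); boundary values are kept.
* A segment of exactly 2 Mb belongs to [2, 4); exactly 16 Mb to
  [16, Inf) — bins are lower-closed.
* Equal FDR at two candidate thresholds: the smaller threshold wins.
* Dosage orientation (which allele is counted) is irrelevant: every
  statistic is orientation-symmetric, and this is property-tested.

## Problem sizes used by the test-suite

Oracle-equivalence suites run on small instances (<= 60 SNPs per
fixture for the brute-force ROH oracle, 500 random fixtures; <= 40 bulls
for dense GLS refits). Simulation acceptance uses the default scenario
above for slope recovery, class attribution and locus ranking, and ten
smaller null replicates (120 bulls, 3 chromosomes) for the type-I check.
The complete suite runs in under two minutes on one CPU.

## A worked run

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)
sim <- simulateGenotypes(cfg)
ph  <- simulatePhenotypes(sim, cfg)
segs <- detectRoh(sim$genotypes)
tab  <- inbreedingTable(sim$genotypes, segs)
grm  <- buildGrm(filterMarkersQC(sim$genotypes))
fit  <- fitAnimalModel(ph, grm,
                       inbreeding = setNames(tab$f_roh, tab$sample_id))
coefTable(fit)[coefTable(fit)$term == "f", ]
heritabilityRepeatability(fitAnimalModel(ph, grm))
```

The same flow, including the scan and region calling, is available as a
single configurable call through `runPipeline()`.
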