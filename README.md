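# rohdep

Genome-wide assessment and mapping of inbreeding depression from SNP
array data with repeated phenotype records — built for semen traits in
dairy bulls (ejaculate volume, sperm concentration, sperm motility), and
applicable to any repeated-records trait with genotyped individuals.

Inbreeding depression is the decline of a trait's mean with increasing
autozygosity. `rohdep` quantifies it in three steps:

**Genomic inbreeding.** Runs of homozygosity (ROH) are called per
individual under explicit constraints (span ≥ 1 Mb, ≥ 15 SNPs, ≤ 1 SNP
per 100 kb average spacing, ≤ 1 heterozygote, ≤ 500 kb between adjacent
SNPs) by an exact maximal-run search, not a sliding-window heuristic.
Two coefficients are computed per animal:

    F_SNP = (OH − EH) / (s − EH),    EH = Σ_j [1 − 2 m_j (1 − m_j)]
    F_ROH = Σ_k L_ROH_k / L_g

plus the decomposition of `F_ROH` into length classes [1,2), [2,4),
[4,8), [8,16), [16,∞) Mb. Since an IBD haplotype from a common ancestor
`g` generations back has expected length `100/(2g)` Mb, the classes
separate ancient from recent inbreeding.

**Regression on inbreeding.** A repeated-records animal model is fitted
by average-information REML:

    y = μ + year_season + centre + interval + n_sample
          + b₁·age + b₂·F + animal + perm + e,
    animal ~ N(0, G σ²ₐ),  perm ~ N(0, I σ²ₚₑ),  e ~ N(0, I σ²ₑ)

with `G` the VanRaden genomic relationship matrix. `b₂` is the
genome-wide depression slope; fitting the five class coefficients
simultaneously attributes it to ROH of a given age.

**Mapping.** Each SNP is tested for a local-homozygosity effect: its
additive dosage and its 0/1 ROH state enter the model together, with
variance components fixed at base-model estimates; significant SNPs are
merged into regions and annotated with genes within ±500 kb. Multiple
testing uses the proportion-based estimate
`FDR = P(1−N) / (N(1−P))`.

A gene-dropping simulator with exactly tracked identity-by-descent
(founder-haplotype labels, Haldane recombination, designed close
matings) generates genotypes and phenotypes with known truth, so the
whole pipeline is testable without any external data.

## Worked example

```r
library(rohdep)

cfg <- simConfig(seed = 1)              # 300 bulls, 10,000 SNPs
sim <- simulateGenotypes(cfg)
ph  <- simulatePhenotypes(sim, cfg)

segs <- detectRoh(sim$genotypes)
tab  <- inbreedingTable(sim$genotypes, segs)
mean(tab$f_roh)
#> [1] 0.093

grm  <- buildGrm(filterMarkersQC(sim$genotypes))
base <- fitAnimalModel(ph, grm)         # no inbreeding covariate
round(heritabilityRepeatability(base), 3)
#>    h2     r
#> 0.108 0.335

fit <- fitAnimalModel(ph, grm,
                      inbreeding = setNames(tab$f_roh, tab$sample_id))
coefTable(fit)[coefTable(fit)$term == "f", ]
#>  term estimate       se         t           p
#>     f -3.56303 1.327741 -2.683529 0.007721796
```

The simulated truth in this run carries a depression slope of −5 trait
units per unit inbreeding; the fitted `b₂ = −3.56 ± 1.33` recovers it
within sampling error and is significant at p < 0.01 — a 1-point
(0.01) increase in `F_ROH` costs about 0.036 units of the trait, ~0.3%
of its mean. `heritabilityRepeatability()` reports `h² ≈ 0.11` and
repeatability `≈ 0.34`, matching the generating variance components
(2.3, 4.5, 14.4). The scan, FDR threshold search and region calling run
the same way from `runScan()`, `minFdrThreshold()` and `callRegions()`,
or everything at once from a YAML config via `runPipeline()` (a thin
command-line wrapper lives in `inst/scripts/rohdep.R`).

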