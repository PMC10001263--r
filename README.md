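# dlahap

Three-locus dog leukocyte antigen (DLA) haplotype analysis: phasing,
breed-level diversity statistics, homozygous-donor transplantation
coverage, and breed-structure PCA.

## The problem

The canine MHC carries two polymorphic class I loci — *DLA-88* and the
*DLA-12/88L* slot, which holds either a *DLA-12* allele or an allele of the
hybrid locus *DLA-88L* — and the class II locus *DLA-DRB1*. The ordered
allele triple on one chromosome is the 88-12/88L-DRB1 haplotype, with one
of two structures (88-12-DRB1 or 88-88L-DRB1). Breed cohorts are strongly
stratified and often inbred, so haplotype homozygosity is common; that
erodes diversity within breeds but makes haplotype-homozygous dogs
attractive as MHC-matched somatic stem-cell donors.

`dlahap` is for researchers analysing unphased three-locus genotype tables
from such cohorts. It provides:

- **Nomenclature**: parsing, validation, formatting and field-1 collapsing
  of MHC-style allele names (`88*004:02`, `DRB1*092:01:1`, tentative
  `88*nov65`), with explicit 12-vs-88L sublocus tags.
- **Phasing** (`phase_cohort`): the tiered homozygote-anchored procedure —
  dogs homozygous at all three loci, then at two, then at one, seed a
  registry of directly observed haplotypes against which the remaining
  heterozygous dogs are resolved; an EM (gene-counting)
  maximum-likelihood phaser (`em_phase`) cross-checks the result.
- **Diversity** (`diversity_report`): per-breed haplotype tables with
  singleton filtering, observed/expected heterozygosity, inbreeding
  coefficient `Fis = 1 - Ho/Hs` (Nei's within-sample gene diversity),
  rarefied haplotype richness `Hr(g) = sum_i [1 - C(2N-N_i, g)/C(2N, g)]`,
  and a seeded Monte-Carlo Hardy–Weinberg test.
- **Donor coverage** (`coverage_curve`): recipients covered by a ranked
  bank of haplotypes observed in homozygous dogs, plus per-breed coverage
  and per-haplotype breed spread.
- **Breed structure** (`pca_breeds`): covariance PCA of breeds on field-1
  haplotype frequencies, and cross-cohort carrier-proportion correlations.
- **Synthetic cohorts** (`simulate_cohort`): a seeded generator of
  breed-stratified cohorts (skewed Dirichlet haplotype pools, shared global
  roster, per-breed inbreeding coefficients) with ground truth retained, so
  every stage is testable without individual-level data.

Breed- and cohort-level summary counts from a published large-scale
Japanese DLA survey (829 dogs, 59 breeds) are bundled (`dla_survey()`) and
used to reproduce its printed cohort statistics.

## Worked example

```r
library(dlahap)

cfg <- default_sim_config(seed = 1)   # 24 survey-scale breeds
co  <- simulate_cohort(cfg)
ph  <- phase_cohort(co$genotypes)
ph
#> Tiered DLA haplotype phasing of 690 dogs
#>   resolved: 550  unresolved: 140
#>   tiers: hom3=257  hom2=0  hom1_ref=26  het_ref=267
#>   registry: 46 haplotypes
```

257 dogs were homozygous at all three loci (their haplotypes are read off
directly), 26 were heterozygous at two loci and 267 at all three but had a
unique registry-consistent phase; 140 dogs had zero or several consistent
candidates and stay unresolved rather than being guessed. Every resolved
diplotype matches the simulation ground truth, and the EM phaser's
posterior modes agree on 100% of resolved dogs:

```r
em <- em_phase(co$genotypes)
r  <- resolved_diplotypes(ph)
e  <- em$diplotypes[match(r$dog_id, em$diplotypes$dog_id), ]
mean(e$hap1 == r$hap1 & e$hap2 == r$hap2)
#> [1] 1
```

Diversity and coverage:

```r
div <- diversity_report(ph, min_dogs = 10, n_perm = 10000, seed = 1)
cohort_summary(div)$mean_ho_3dp
#> [1] 0.533

cov <- coverage_curve(ph)
cov[c(5, 10), c("rank", "cum_matched", "cum_pct")]
#>    rank cum_matched cum_pct
#> 5     5         172    31.3
#> 10   10         285    51.8
```

A bank built from the 10 most frequent homozygote-observed haplotypes
would cover 51.8% of the assigned dogs in this synthetic cohort.

The numbered scripts under `analysis/` run these stages end to end
(`01_simulate.R` … `06_survey_counts.R`), writing their tables under
`results/`.

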