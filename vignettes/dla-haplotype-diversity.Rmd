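---
title: "Three-locus DLA haplotype phasing, diversity and donor coverage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-locus DLA haplotype phasing, diversity and donor coverage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The dog major histocompatibility complex — the dog leukocyte antigen (DLA)
region — carries two relatively polymorphic class I loci, *DLA-88* and the
*DLA-12/88L* slot, and the highly polymorphic class II locus *DLA-DRB1*.
The *DLA-12/88L* slot is occupied on any one chromosome either by a
*DLA-12* allele or by an allele of the hybrid locus *DLA-88L*, so every
three-locus haplotype has one of two structures: 88-12-DRB1 or 88-88L-DRB1.
Because pure-breed dogs are strongly stratified and often inbred, breed
cohorts show high haplotype homozygosity; this is a problem for biological
fitness but an opportunity for MHC-matched somatic stem-cell
transplantation, where cell lines derived from haplotype-homozygous donors
could serve many matched recipients.

`dlahap` implements the full analysis chain for unphased three-locus
genotype tables: allele nomenclature handling, haplotype phasing, per-breed
diversity statistics, donor-bank coverage modelling, and breed-structure
PCA, plus a synthetic cohort generator so every stage can be exercised and
validated without individual-level data.

## Nomenclature

Allele names follow MHC conventions, `locus*field1:field2:...` with up to
four numeric fields (e.g. `88*004:02`, `DRB1*092:01:1`); tentative alleles
awaiting official names carry a single `nov<number>` token and are treated
as atomic units at every resolution, since they have no official field
structure. *DLA-88L* alleles are officially published under the `DLA-88*`
prefix; we instead carry the sublocus explicitly (`88L*`) in all stored
names — it is information required by the structure classification and must
never be inferred from the name — and provide an "official" formatting
style that restores the published prefix. Field-1 collapsing
(`collapse_field1()`) keeps only the first name field, grouping alleles
whose peptide-binding regions are similar; it is idempotent, and whether a
`nov` allele would belong to some numeric field-1 group is unknowable, so
`nov` alleles always remain their own group.

Canonical ordering of alleles (locus block 88, 12, 88L, DRB1; numeric
fields compared elementwise; tentative alleles last) gives deterministic
unordered pairs, deterministic table ordering and deterministic tie-breaks
throughout.

## Tiered homozygote-anchored phasing

With `h` heterozygous loci a genotype admits `2^max(h-1, 0)`
phase-consistent diplotypes. Dogs with `h <= 1` have a unique phase; they
are resolved first (tiers `hom3` and `hom2`) and their haplotypes populate
a registry of directly observed haplotypes. Each remaining dog keeps the
candidate diplotypes whose two haplotypes are both in the registry; if
exactly one candidate survives the dog is resolved (tier `hom1_ref` for
`h = 2`, `het_ref` for `h = 3`), otherwise it stays unresolved and its
candidate count is reported. Two design points were genuinely open:

* **Ties are never frequency-broken.** A dog whose surviving candidates
  share one haplotype but differ in the other stays unresolved — no partial
  credit. Frequency-based adjudication is available separately through the
  EM phaser's posterior modes, and keeping the two mechanisms apart makes
  the tiered output auditable.
* **`resolve_and_extend` (default off).** By default the registry holds
  only haplotypes seen in dogs with at most one heterozygous locus, the
  strictly homozygote-anchored reading. With the flag on, both haplotypes
  of a newly resolved heterozygous dog join the registry and resolution
  iterates to a fixpoint (bounded by `max_rounds`, default 10); this is a
  superset that can only resolve more dogs, never differently, which the
  test suite verifies.

The EM cross-check (`em_phase()`) is standard gene counting over the
haplotype space spanned by all candidates: uniform initial frequencies,
Hardy–Weinberg diplotype weights, expected-count updates. The
log-likelihood is non-decreasing by construction and the implementation
stops when its change falls below `tol` (default 1e-8, `max_iter` 1000).
On cohorts at the standard synthetic scale the EM posterior-mode diplotypes
agree with the tiered assignments on more than 99% of resolved dogs,
mirroring the role of a maximum-likelihood phaser as confirmation of the
manual tiered procedure.

## Diversity statistics

All statistics treat the three-locus haplotype as one multi-allelic marker.

* **Ho** is exactly `1 - n_homozygous / N` over dogs with an assigned
  diplotype.
* **He** defaults to the uncorrected gene diversity `1 - sum(p^2)`; the
  Nei small-sample corrected `(2N/(2N-1)) (1 - sum(p^2))` is always
  computed alongside. The uncorrected form is the default because the
  common survey software reports it; both are in every report so the choice
  is transparent.
* **Fis** is `1 - Ho/Hs` with Nei's unbiased within-sample gene diversity
  `Hs = (N/(N-1)) (1 - sum(p^2) - Ho/(2N))`, the estimator family used by
  FSTAT-style software; the naive `1 - Ho/He` is reported alongside.
  Monomorphic cohorts are not applicable (`NA`).
* **Hr(g)**, rarefied haplotype richness, uses exact hypergeometric
  non-observation probabilities
  `sum_i [1 - C(2N - N_i, g) / C(2N, g)]`, computed on log binomial
  coefficients for stability. `g` defaults to the smallest `2N` across
  reported breeds (20 gene copies when the smallest breed has 10 dogs).
* **HWE** is a Monte-Carlo exact test: the chi-squared discrepancy of
  diplotype counts from Hardy–Weinberg expectations under the observed
  haplotype frequencies, with the null generated by randomly re-pairing the
  `2N` observed chromosomes and `p = (1 + #{null >= obs}) / (1 + n_perm)`
  (default `n_perm` 10000, seeded). An asymptotic chi-squared p-value
  (df `K(K-1)/2`) is reported for reference, but the permutation p is the
  headline number because expected genotype counts are tiny in small
  breeds. Significance is annotated at 0.05 and 0.001 with no
  multiple-testing correction, matching common practice in these surveys.

Printed-table conventions: percentages are rounded half away from zero at
the printed precision (`percent(..., mode = "half-up")`), except that some
published cohort-level rates are truncated rather than rounded, so the
formatter also has `mode = "truncate"`. Both conventions are exposed
because the bundled survey tables themselves mix them.

## Donor coverage

Donor haplotypes are those observed in at least one homozygous dog, ranked
by cohort-wide frequency (label-order tie-break). A recipient is covered at
rank `k` if its diplotype contains at least one of the top-`k` donor
haplotypes — host-versus-graft matching only; graft-versus-host direction
and DQ-locus extension are out of scope. The default denominator is the
number of dogs with an assigned diplotype, with a flag for the full-cohort
denominator: published coverage percentages are not all consistent with a
single denominator, so the package reports counts and lets the formatter
choose. Mongrels are excluded from per-haplotype breed-spread counts but
included in cohort-level coverage.

## Breed structure

The breed-by-haplotype frequency matrix is computed at field-1 resolution
(full resolution optional); each row is a breed's haplotype frequency
vector over twice its assigned dogs. PCA is covariance PCA on the raw
frequencies — columns are centred but not standardised, because frequencies
already share a scale; a standardised option exists since the exact
transform used by common survey software is not documented. Components come
from the SVD of the centred matrix with a deterministic sign convention
(largest-magnitude loading positive), so results are invariant to row
order. Cross-cohort comparison of per-allele carrier proportions uses
Pearson correlation over the union of alleles seen in either cohort, with
absences as zeros; a zero-variance vector makes the correlation not
applicable rather than an error.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes in
real breed-stratified DLA surveys:

* **Scale.** The default configuration has 24 breeds whose sizes (10–49
  dogs), pool sizes (3–27 haplotypes) and inbreeding coefficients (−0.21 to
  0.315) are taken from the per-breed values of the bundled published
  survey table, so the default cohort *is* the survey-scale condition.
* **Skew.** Pool frequencies are symmetric Dirichlet draws with
  concentration 0.35, giving the strongly skewed distributions seen in real
  breeds, where one haplotype often exceeds 50% within a breed.
* **Structure split.** A fraction `frac_88L` (default 0.21, the share of
  88-88L copies among the survey's recurrent haplotypes) of each pool
  carries the 88L structure.
* **Sharing.** Breeds draw their pools from a shared global roster of 80
  haplotypes, so haplotypes recur across breeds and the PCA grouping
  behaviour is exercised. Allele rosters pair consecutive alleles into
  common field-1 groups so that field-1 collapsing genuinely merges
  columns.
* **Inbreeding.** With probability `max(fis, 0)` a dog's two haplotypes
  are one pool draw (identical by descent), else two independent draws;
  this yields a haplotype-level Fis close to the configured value in
  expectation, and parameter-recovery tests confirm ±0.05 at 2000 dogs.
  Negative `fis` rejects homozygous draws with probability `|fis|`, which
  attenuates rather than exactly hits strongly negative targets — the
  achievable deficit is bounded by the rejection scheme, and a config with
  a single haplotype and negative `fis` is an error.
* **Reproducibility.** One root seed; per-breed child streams are derived
  by hashing the breed name, so adding or reordering breeds does not
  perturb the other breeds' draws, and the same configuration and seed give
  byte-identical cohorts.

What the generator does **not** model: mutation, recombination between the
three loci, linkage-disequilibrium decay, genotyping error, and pedigree
structure beyond the one-parameter identity-by-descent mixture. Passing
tests on synthetic cohorts therefore demonstrate the correctness of the
estimators and of the phasing logic under the assumed generative model, not
robustness to genotyping artefacts in real data.

## Problem sizes and numerical choices

The validation suite uses 20 cohorts of 2000 dogs with 8-haplotype pools
and Fis 0.1 for phasing soundness and EM agreement, 20 cohorts at Fis 0.2
for inbreeding recovery, 200 null cohorts of 50 dogs (199 re-pairings each)
for the HWE type-I error, exhaustive enumeration (all 15 two-copy
subsamples; all 720 chromosome permutations at 2N = 6) for the rarefaction
and HWE oracles, and direct SVDs for the PCA oracle. These sizes make the
full suite run in well under ten minutes on a single core while keeping
Monte-Carlo standard errors far below the tolerances being asserted.

Degenerate inputs are handled explicitly: empty cohorts and zero resolved
dogs are errors; monomorphic cohorts give `NA` for Fis and the HWE p-value;
a cohort without homozygotes gives an empty donor ranking with a warning;
breeds without resolved dogs are dropped from the frequency matrix with a
warning; `g` beyond `2N` and non-normalised frequency vectors are errors.

## Known limitations

* The bundled published survey tables are cohort- and breed-level counts;
  per-dog data are not distributed, so the published He/Fis/Hr values
  (which depend on individual diplotypes) cannot be recomputed here and are
  carried for reference only. Two rows of the published per-breed table
  print Ho values computed with the total (assigned + unassigned) dog count
  while the rest use assigned dogs; this package always uses the assigned
  count, the definition used by its own estimator, which shifts the
  recomputed 24-breed mean Ho from the printed 0.736 to 0.735.
* The tiered phaser is deliberately conservative; cohorts with many rare
  haplotypes leave more dogs unresolved than a likelihood-based assignment
  would. The EM output is the right tool when a best guess is required for
  every dog.
* The EM phaser assumes Hardy–Weinberg pairing within the cohort it is
  given; run it per breed when breeds deviate strongly.
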