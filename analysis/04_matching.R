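#!/usr/bin/env Rscript
# Homozygous-donor bank modelling: rank donor haplotypes by frequency,
# accumulate recipient coverage down the ranking, and summarise per-breed
# coverage by each breed's top haplotype and each haplotype's breed spread.

suppressPackageStartupMessages(library(dlahap))
g <- read_genotypes("results/cohort.genotypes.tsv")
ph <- phase_cohort(g)

donors <- rank_donor_haplotypes(ph)
cov <- coverage_curve(ph, donors)
write.table(as.data.frame(cov), "results/cohort.coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d donor haplotypes observed in homozygotes", length(donors)))
for (k in c(5, 10, length(donors))) {
  if (k <= length(donors)) {
    message(sprintf("coverage at %d donors: %d dogs (%.1f%%)",
                    k, cov$cum_matched[k], cov$cum_pct[k]))
  }
}

bcov <- breed_top_coverage(ph, min_dogs = 10)
write.table(bcov, "results/cohort.breed_coverage.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d breeds reach >= 50%% coverage with their top haplotype",
                sum(bcov$pct >= 50), nrow(bcov)))

tab <- build_haplotype_table(ph)
sp <- breed_spread(tab, ph)
write.table(sp, "results/cohort.breed_spread.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
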