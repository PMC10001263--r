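#!/usr/bin/env Rscript
# Haplotype frequency table (with the recurrent-haplotype filter), per-breed
# diversity indices (Ho, He, Fis, rarefied richness, Monte-Carlo HWE) and
# the per-allele frequency / carrier summary.

suppressPackageStartupMessages(library(dlahap))
g <- read_genotypes("results/cohort.genotypes.tsv")
ph <- phase_cohort(g)

tab <- build_haplotype_table(ph, min_count = 2)
print(tab)
message(sprintf("structure split over retained copies: %s",
                paste(sprintf("%s %.1f%%", tab$structure_split$structure,
                              tab$structure_split$pct), collapse = " / ")))
write.table(tab$entries, "results/cohort.haplotypes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

div <- diversity_report(ph, min_dogs = 10, n_perm = 10000, seed = 1)
write.table(div, "results/cohort.diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cs <- cohort_summary(div)
message(sprintf("mean per-breed Ho over %d breeds: %.3f",
                cs$n_breeds, cs$mean_ho_3dp))
message(sprintf("HWE deviations at p<0.05: %d breeds", sum(div$sig_0.05)))

al <- allele_summary(g)
write.table(al, "results/cohort.alleles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- al[which.max(al$carrier_proportion), ]
message(sprintf("most carried allele: %s (%.1f%% of dogs)",
                top$allele, 100 * top$carrier_proportion))
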