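#!/usr/bin/env Rscript
# Breed structure: field-1 breed-by-haplotype frequency matrix, covariance
# PCA of the breeds, and a re-analysis after dropping the two most outlying
# breeds on PC1/PC2 (the analogue of removing breeds dominated by a single
# haplotype).

suppressPackageStartupMessages(library(dlahap))
g <- read_genotypes("results/cohort.genotypes.tsv")
ph <- phase_cohort(g)

div <- diversity_report(ph, min_dogs = 10, n_perm = 100, seed = 1)
m <- breed_frequency_matrix(ph, breeds = div$breed)
write.table(data.frame(breed = rownames(m), m, check.names = FALSE),
            "results/cohort.matrix.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

p <- pca_breeds(m)
print(p)
write.table(data.frame(breed = rownames(p$coordinates), p$coordinates,
                       check.names = FALSE),
            "results/cohort.pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(component = seq_along(p$eigenvalues),
                       eigenvalue = p$eigenvalues,
                       contribution = p$contribution),
            "results/cohort.scree.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

d2 <- sqrt(p$coordinates[, 1]^2 + p$coordinates[, 2]^2)
outliers <- names(sort(d2, decreasing = TRUE))[1:2]
message("outlier breeds on PC1/PC2: ", paste(outliers, collapse = ", "))
p2 <- pca_breeds(m, drop_breeds = outliers)
write.table(data.frame(breed = rownames(p2$coordinates), p2$coordinates,
                       check.names = FALSE),
            "results/cohort.pca_no_outliers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("PC1+PC2 contribution: %.1f%% with outliers, %.1f%% without",
                100 * sum(p$contribution[1:2]),
                100 * sum(p2$contribution[1:2])))
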