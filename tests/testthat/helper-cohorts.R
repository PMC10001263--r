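# Shared fixtures, built in code.

# one-breed cohort at the standard synthetic setting
std_cohort <- function(seed, n = 2000, K = 8, fis = 0.1, alpha = 0.5) {
  cfg <- sim_config(list(
    breed_config("TestBreed", n, K, dirichlet_alpha = alpha, fis = fis)
  ), seed = seed)
  simulate_cohort(cfg)
}

# one-breed cohort with an explicitly fixed haplotype pool
pool_cohort <- function(seed, n, haps, freqs, fis = 0) {
  pool <- data.frame(haplotype = haps, freq = freqs)
  cfg <- sim_config(list(
    breed_config("PoolBreed", n, length(haps), fis = fis, pool = pool)
  ), seed = seed)
  simulate_cohort(cfg)
}

# small named haplotypes reused across tests
HAP_A <- "88*001:01|12*001:01|DRB1*001:01"
HAP_B <- "88*002:01|12*002:01|DRB1*002:01"
HAP_C <- "88*003:01|88L*017:01|DRB1*009:01"
HAP_D <- "88*004:02|12*001:01|DRB1*006:01"

# genotype row from two haplotype strings (projection of a known diplotype)
genotype_row <- function(id, breed, h1, h2) {
  project_genotypes(data.frame(dog_id = id, breed = breed,
                               hap1 = h1, hap2 = h2,
                               stringsAsFactors = FALSE))
}

# independent brute-force enumeration of phase-consistent diplotypes:
# assign each locus's two alleles to two chromosomes over all 2^3 ordered
# assignments, then deduplicate unordered haplotype pairs
brute_force_diplotypes <- function(g) {
  pairs <- list(c(g$a88_1, g$a88_2),
                c(g$a12_88L_1, g$a12_88L_2),
                c(g$drb1_1, g$drb1_2))
  seen <- character(0)
  out <- list()
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    bits <- c(b1, b2, b3)
    h1 <- paste(mapply(function(p, b) p[1 + b], pairs, bits), collapse = "|")
    h2 <- paste(mapply(function(p, b) p[2 - b], pairs, bits), collapse = "|")
    key <- paste(sort(c(h1, h2)), collapse = "//")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- sort(c(h1, h2))
    }
  }
  out
}

# independent chi-squared HWE statistic (oracle for hwe_test internals)
oracle_hwe_stat <- function(hap1, hap2) {
  N <- length(hap1)
  haps <- sort(unique(c(hap1, hap2)))
  p <- as.vector(table(factor(c(hap1, hap2), levels = haps))) / (2 * N)
  stat <- 0
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    obs <- if (i == j) {
      sum(hap1 == haps[i] & hap2 == haps[i])
    } else {
      sum((hap1 == haps[i] & hap2 == haps[j]) |
            (hap1 == haps[j] & hap2 == haps[i]))
    }
    e <- if (i == j) N * p[i]^2 else 2 * N * p[i] * p[j]
    if (e > 0) stat <- stat + (obs - e)^2 / e
  }
  stat
}
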