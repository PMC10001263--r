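toy_diplotypes <- function() {
  # A: 3 copies (1 hom dog), B: 2, C: 1 (singleton, 88L structure)
  data.frame(
    dog_id = c("d1", "d2", "d3"), breed = c("X", "X", "Y"),
    hap1 = c(HAP_A, HAP_A, HAP_B),
    hap2 = c(HAP_A, HAP_B, HAP_C),
    stringsAsFactors = FALSE
  )
}

test_that("haplotype table counts, flags and conservation are exact", {
  tab <- build_haplotype_table(toy_diplotypes(), min_count = 2)
  e <- tab$entries
  expect_equal(sum(e$count), 2 * tab$n_dogs_assigned)
  expect_equal(e$count[e$haplotype == HAP_A], 3)
  expect_equal(e$frequency[e$haplotype == HAP_A], 3 / 6)
  expect_equal(e$n_dogs_with[e$haplotype == HAP_A], 2)
  expect_equal(e$n_homozygous_dogs[e$haplotype == HAP_A], 1)
  expect_identical(e$singleton, e$count == 1L)
  expect_identical(e$retained, e$count >= 2L)
  # structure split over the retained set only (A and B are 88-12)
  expect_equal(tab$structure_split$copies,
               c(5L, 0L))
  expect_error(build_haplotype_table(toy_diplotypes()[0, ]), "zero resolved")
})

test_that("frequencies and splits reproduce printed percentages from counts", {
  # counts 68 and 62 over 2 x 803 chromosomes
  expect_equal(percent(68 / (2 * 803), 2), 4.23)
  expect_equal(percent(62 / (2 * 803), 2), 3.86)
  # structure split 1228 / 319 over 1547 retained copies
  expect_equal(percent(1228 / 1547), 79.4)
  expect_equal(percent(319 / 1547), 20.6)
})

test_that("observed heterozygosity is the exact homozygote complement", {
  expect_equal(round_half_up(observed_heterozygosity(35, 24), 3), 0.314)
  expect_equal(round_half_up(observed_heterozygosity(20, 9), 3), 0.550)
  expect_equal(observed_heterozygosity(7, 0), 1)
  expect_error(observed_heterozygosity(0, 0), "positive")
  expect_error(observed_heterozygosity(5, 6), "between 0 and N")
})

test_that("expected heterozygosity matches direct summation", {
  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(1, N = 10, mode = "unbiased"), 0)
  set.seed(31)
  for (i in 1:20) {
    p <- stats::runif(sample(2:12, 1)); p <- p / sum(p)
    expect_equal(expected_heterozygosity(p), 1 - sum(p * p))
    n <- sample(5:50, 1)
    expect_equal(expected_heterozygosity(p, N = n, mode = "unbiased"),
                 (2 * n / (2 * n - 1)) * (1 - sum(p * p)))
    expect_gte(expected_heterozygosity(p, N = n, mode = "unbiased"),
               expected_heterozygosity(p))
  }
  expect_error(expected_heterozygosity(c(0.4, 0.4)), "sum to 1")
})

test_that("Fis is 1 for all-homozygous cohorts and NA when monomorphic", {
  allhom <- data.frame(dog_id = c("a", "b"), breed = "B",
                       hap1 = c(HAP_A, HAP_B), hap2 = c(HAP_A, HAP_B),
                       stringsAsFactors = FALSE)
  expect_equal(inbreeding_fis(allhom)$fis, 1)
  mono <- data.frame(dog_id = c("a", "b"), breed = "B",
                     hap1 = c(HAP_A, HAP_A), hap2 = c(HAP_A, HAP_A),
                     stringsAsFactors = FALSE)
  expect_true(is.na(inbreeding_fis(mono)$fis))
})

test_that("rarefied richness equals the exhaustive subsample oracle", {
  # single haplotype: 1 at any g; g = 2N: all distinct haplotypes
  expect_equal(haplotype_richness(5, 3), 1)
  expect_equal(haplotype_richness(c(3, 2, 1), 6), 3)
  # counts (3,2,1), g = 2: enumerate all C(6,2) subsamples
  copies <- rep(c("a", "b", "c"), c(3, 2, 1))
  subs <- utils::combn(6, 2)
  oracle <- mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
  expect_equal(haplotype_richness(c(3, 2, 1), 2), oracle)
  # monotone non-decreasing in g
  hr <- sapply(1:6, function(g) haplotype_richness(c(3, 2, 1), g))
  expect_true(all(diff(hr) >= -1e-12))
  expect_error(haplotype_richness(c(3, 2, 1), 7), "exceed")
  # independent implementation: vegan's individual-based rarefaction uses
  # the same hypergeometric expectation
  counts <- c(12, 7, 5, 3, 1)
  for (g in c(2, 5, 14)) {
    expect_equal(haplotype_richness(counts, g),
                 as.vector(vegan::rarefy(counts, g)))
  }
})

test_that("HWE Monte-Carlo p-value is seeded, detects disequilibrium, and matches exhaustive re-pairing on a tiny cohort", {
  allhom <- data.frame(
    dog_id = sprintf("d%02d", 1:50), breed = "B",
    hap1 = rep(c(HAP_A, HAP_B), 25), hap2 = rep(c(HAP_A, HAP_B), 25),
    stringsAsFactors = FALSE
  )
  h1 <- hwe_test(allhom, n_perm = 2000, seed = 7)
  expect_lt(h1$p_mc, 0.01)
  expect_identical(h1$p_mc, hwe_test(allhom, n_perm = 2000, seed = 7)$p_mc)

  # tiny cohort, 2N = 6: exhaustive re-pairing distribution over all 720
  # permutations of the chromosome vector
  tiny <- data.frame(dog_id = c("a", "b", "c"), breed = "B",
                     hap1 = c(HAP_A, HAP_A, HAP_B),
                     hap2 = c(HAP_A, HAP_B, HAP_B),
                     stringsAsFactors = FALSE)
  chrom <- c(tiny$hap1, tiny$hap2)
  obs <- oracle_hwe_stat(tiny$hap1, tiny$hap2)
  idx <- seq_len(6)
  # enumerate permutations without external packages
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  stats_null <- vapply(perm_rec(idx), function(pm) {
    oracle_hwe_stat(chrom[pm[1:3]], chrom[pm[4:6]])
  }, numeric(1))
  p_exact <- mean(stats_null >= obs - 1e-12)
  h2 <- hwe_test(tiny, n_perm = 20000, seed = 11)
  expect_lt(abs(h2$p_mc - p_exact), 0.02)
  expect_equal(h2$statistic, obs)

  mono <- data.frame(dog_id = c("a", "b"), breed = "B",
                     hap1 = HAP_A, hap2 = HAP_A, stringsAsFactors = FALSE)
  expect_true(is.na(hwe_test(mono, n_perm = 10)$p_mc))
})

test_that("allele summary counts copies and carriers exactly", {
  truth <- data.frame(
    dog_id = c("d1", "d2", "d3"), breed = "B",
    hap1 = c(HAP_A, HAP_A, HAP_B), hap2 = c(HAP_A, HAP_B, HAP_C),
    stringsAsFactors = FALSE
  )
  g <- project_genotypes(truth)
  s <- allele_summary(g)
  a88_A <- split_haplotype(HAP_A)$a88
  row <- s[s$allele == a88_A, ]
  expect_equal(row$count, 3L)       # direct count oracle
  expect_equal(row$frequency, 3 / 6)
  expect_equal(row$carriers, 2L)
  expect_equal(row$carrier_proportion, 2 / 3)
  # per-slot copies sum to 2N
  expect_true(all(tapply(s$count, s$locus_slot, sum) == 2 * nrow(g)))
  # printed carrier percentage from counts
  expect_equal(percent(545 / 829), 65.7)
})

test_that("per-breed report and cohort summary are consistent", {
  cfg <- sim_config(list(
    breed_config("P", 60, 5, dirichlet_alpha = 0.6, fis = 0.1),
    breed_config("Q", 40, 7, dirichlet_alpha = 0.6, fis = 0)
  ), seed = 19)
  co <- simulate_cohort(cfg)
  ph <- phase_cohort(co$genotypes)
  rep <- diversity_report(ph, min_dogs = 10, n_perm = 300, seed = 3)
  expect_setequal(rep$breed, c("P", "Q"))
  expect_equal(rep$Ho, 1 - rep$n_homozygous / rep$N)
  expect_true(all(rep$Hr <= rep$n_haplotypes + 1e-9))
  expect_true(all(rep$He_unbiased >= rep$He_biased))
  # unweighted mean Ho; invariant to breed order
  cs <- cohort_summary(rep)
  expect_equal(cs$mean_ho, mean(rep$Ho))
  expect_equal(cohort_summary(rep[2:1, ])$mean_ho, cs$mean_ho)
  expect_equal(cohort_summary(rep[1, , drop = FALSE])$mean_ho, rep$Ho[1])
})
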