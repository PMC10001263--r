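test_that("simulation is deterministic given config and seed", {
  co1 <- std_cohort(seed = 5, n = 200)
  co2 <- std_cohort(seed = 5, n = 200)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$genotypes, co2$genotypes)
  co3 <- std_cohort(seed = 6, n = 200)
  expect_false(identical(co1$truth, co3$truth))
})

test_that("adding a breed does not perturb the other breeds' draws", {
  b1 <- breed_config("Alpha", 50, 5)
  b2 <- breed_config("Beta", 40, 6)
  b3 <- breed_config("Gamma", 30, 4)
  co12 <- simulate_cohort(sim_config(list(b1, b2), seed = 9))
  co123 <- simulate_cohort(sim_config(list(b1, b2, b3), seed = 9))
  t12 <- co12$truth[co12$truth$breed %in% c("Alpha", "Beta"),
                    c("breed", "hap1", "hap2")]
  t123 <- co123$truth[co123$truth$breed %in% c("Alpha", "Beta"),
                      c("breed", "hap1", "hap2")]
  expect_identical(t12, t123)
})

test_that("degenerate pools behave as stated", {
  # single haplotype: frequency 1, every dog homozygous for it
  co <- std_cohort(seed = 1, n = 30, K = 1)
  pool <- co$pools[[1]]
  expect_equal(nrow(pool), 1L)
  expect_equal(pool$freq, 1)
  expect_true(all(co$truth$hap1 == pool$haplotype &
                    co$truth$hap2 == pool$haplotype))
  # frac_88L = 0: every pool haplotype has the 88-12 structure
  cfg <- sim_config(list(breed_config("B", 10, 6)), frac_88L = 0, seed = 2)
  expect_true(all(build_breed_pool(cfg, "B")$structure == "88-12-DRB1"))
  # floor(frac_88L * K) pool haplotypes carry the 88L structure
  cfg <- sim_config(list(breed_config("B", 10, 10)), frac_88L = 0.21,
                    seed = 2)
  expect_equal(sum(build_breed_pool(cfg, "B")$structure == "88-88L-DRB1"),
               floor(0.21 * 10))
})

test_that("pool frequencies follow the symmetric Dirichlet", {
  # alpha large, K = 4: mean frequency near 1/4 across many draws
  freqs <- sapply(1:1000, function(s) {
    cfg <- sim_config(list(breed_config("B", 5, 4, dirichlet_alpha = 50)),
                      seed = s)
    build_breed_pool(cfg, "B", build_global_pool(cfg))$freq
  })
  expect_equal(dim(freqs), c(4L, 1000L))
  expect_true(all(abs(rowMeans(freqs) - 0.25) < 0.01))
  # Dirichlet(50) variance: p(1-p)/(4*50+1)
  expect_true(all(abs(apply(freqs, 1, var) - 0.25 * 0.75 / 201) < 3e-4))
})

test_that("infeasible pool requests raise config errors", {
  cfg <- sim_config(list(breed_config("B", 10, 70)), frac_88L = 0,
                    n_global_haplotypes = 80, seed = 1)
  # 80-hap roster holds floor(0.21*80)=16 88L haplotypes at default frac;
  # here frac=0 so 80 are 12-structure and 70 is feasible, but 90 is not
  expect_silent(build_breed_pool(cfg, "B"))
  cfg2 <- sim_config(list(breed_config("B", 10, 90)), frac_88L = 0,
                     n_global_haplotypes = 80, seed = 1)
  expect_error(build_breed_pool(cfg2, "B"), "infeasible")
  expect_error(
    build_global_pool(sim_config(list(breed_config("B", 5, 4)),
                                 allele_pool_sizes = c("88" = 2, "12" = 2,
                                                       "88L" = 1, "DRB1" = 2),
                                 n_global_haplotypes = 50, seed = 1)),
    "infeasible")
})

test_that("the unphased table is exactly the projection of the truth", {
  co <- std_cohort(seed = 3, n = 300, K = 6)
  g <- co$genotypes
  for (i in sample(nrow(g), 25)) {
    s1 <- split_haplotype(co$truth$hap1[i])
    s2 <- split_haplotype(co$truth$hap2[i])
    expect_setequal(c(g$a88_1[i], g$a88_2[i]), c(s1$a88, s2$a88))
    expect_setequal(c(g$a12_88L_1[i], g$a12_88L_2[i]),
                    c(s1$a12_88L, s2$a12_88L))
    expect_setequal(c(g$drb1_1[i], g$drb1_2[i]), c(s1$drb1, s2$drb1))
    # canonical sorted pairs
    expect_identical(g$a88_1[i], sort_alleles(c(g$a88_1[i], g$a88_2[i]))[1])
  }
})

test_that("inbreeding model reproduces the analytic homozygote fraction", {
  # fis = 0, two haplotypes at p = (0.5, 0.5): P(hom) = sum p^2 = 0.5
  co <- pool_cohort(seed = 4, n = 10000, haps = c(HAP_A, HAP_B),
                    freqs = c(0.5, 0.5), fis = 0)
  hom <- mean(co$truth$hap1 == co$truth$hap2)
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(hom - 0.5), 3 * se)

  # fis = 1: every dog homozygous
  co1 <- pool_cohort(seed = 5, n = 200, haps = c(HAP_A, HAP_B),
                     freqs = c(0.3, 0.7), fis = 1)
  expect_true(all(co1$truth$hap1 == co1$truth$hap2))

  # negative fis by homozygote rejection: with q = |fis|,
  # P(hom) = sum(p^2)(1-q) / (1 - sum(p^2) q); at p=(.5,.5), q=.5 -> 1/3
  co2 <- pool_cohort(seed = 6, n = 10000, haps = c(HAP_A, HAP_B),
                     freqs = c(0.5, 0.5), fis = -0.5)
  hom2 <- mean(co2$truth$hap1 == co2$truth$hap2)
  expect_lt(abs(hom2 - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 10000))

  # negative fis with a single haplotype cannot be honoured
  expect_error(pool_cohort(seed = 7, n = 10, haps = HAP_A, freqs = 1,
                           fis = -0.2), "negative fis")
})

test_that("empirical haplotype frequencies converge to the pool", {
  freqs <- c(0.55, 0.25, 0.12, 0.08)
  haps <- c(HAP_A, HAP_B, HAP_C, HAP_D)
  co <- pool_cohort(seed = 8, n = 10000, haps = haps, freqs = freqs)
  emp <- table(factor(c(co$truth$hap1, co$truth$hap2), levels = haps)) /
    (2 * 10000)
  se <- sqrt(freqs * (1 - freqs) / (2 * 10000))
  expect_true(all(abs(as.vector(emp) - freqs) < 3 * se + 1e-12))
})

test_that("downstream Fis estimation recovers the configured value", {
  est <- sapply(1:6, function(s) {
    co <- std_cohort(seed = 100 + s, n = 2000, fis = 0.2)
    inbreeding_fis(co$truth)$fis
  })
  expect_lt(abs(mean(est) - 0.2), 0.05)
  co0 <- std_cohort(seed = 200, n = 2000, fis = 0)
  expect_lt(abs(inbreeding_fis(co0$truth)$fis), 0.05)
})
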