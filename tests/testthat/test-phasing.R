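test_that("diplotype enumeration yields 2^(h-1) candidates, matching brute force", {
  hA <- HAP_A; hB <- HAP_B; hC <- HAP_C
  cases <- list(
    list(g = genotype_row("d", "B", hA, hA), n = 1L),             # h = 0
    list(g = genotype_row("d", "B", hA,
           "88*001:01|12*001:01|DRB1*002:01"), n = 1L),           # h = 1
    list(g = genotype_row("d", "B", hA,
           "88*002:01|12*002:01|DRB1*001:01"), n = 2L),           # h = 2
    list(g = genotype_row("d", "B", hA, hB), n = 4L)              # h = 3
  )
  for (cs in cases) {
    d <- enumerate_diplotypes(cs$g)
    expect_equal(nrow(d), cs$n)
    got <- sort(paste(pmin(d$hap1, d$hap2), pmax(d$hap1, d$hap2), sep = "//"))
    want <- sort(vapply(brute_force_diplotypes(cs$g),
                        function(p) paste(p, collapse = "//"), character(1)))
    expect_identical(got, want)
  }
  # a fully homozygous genotype yields the homozygous diplotype
  d0 <- enumerate_diplotypes(cases[[1]]$g)
  expect_identical(d0$hap1, d0$hap2)
})

test_that("dogs with at most one heterozygous locus are forced in pass 1", {
  g <- rbind(
    genotype_row("hom", "B", HAP_A, HAP_A),
    genotype_row("het_drb1", "B", HAP_A, "88*001:01|12*001:01|DRB1*005:01")
  )
  ph <- phase_cohort(g)
  a <- ph$assignments
  expect_identical(a$status, c("resolved", "resolved"))
  expect_identical(a$tier, c("hom3", "hom2"))
  expect_identical(a$hap1[1], HAP_A)
  expect_setequal(c(a$hap1[2], a$hap2[2]),
                  c(HAP_A, "88*001:01|12*001:01|DRB1*005:01"))
  expect_error(phase_cohort(g[0, ]), "empty cohort")
})

test_that("registry resolution is sound and accounts for every unresolved dog", {
  co <- std_cohort(seed = 42)
  ph <- phase_cohort(co$genotypes)
  r <- resolved_diplotypes(ph)
  tr <- co$truth[match(r$dog_id, co$truth$dog_id), ]
  # soundness: a resolved dog is never assigned a wrong diplotype
  expect_true(all(r$hap1 == tr$hap1 & r$hap2 == tr$hap2))
  # unresolved dogs are exactly those whose true pair is not the unique
  # registry-consistent candidate (brute-force candidate filtering)
  un <- ph$assignments[ph$assignments$status == "unresolved", ]
  g <- co$genotypes
  for (id in un$dog_id) {
    cand <- enumerate_diplotypes(g[g$dog_id == id, , drop = FALSE])
    ok <- cand$hap1 %in% ph$registry$haplotype &
      cand$hap2 %in% ph$registry$haplotype
    expect_true(sum(ok) != 1L)
    expect_equal(un$n_consistent[un$dog_id == id], sum(ok))
  }
})

test_that("tier bookkeeping matches the dogs' heterozygosity", {
  co <- std_cohort(seed = 21, n = 500)
  ph <- phase_cohort(co$genotypes)
  a <- ph$assignments
  h <- (co$genotypes$a88_1 != co$genotypes$a88_2) +
    (co$genotypes$a12_88L_1 != co$genotypes$a12_88L_2) +
    (co$genotypes$drb1_1 != co$genotypes$drb1_2)
  expect_true(all(h[!is.na(a$tier) & a$tier == "hom3"] == 0))
  expect_true(all(h[!is.na(a$tier) & a$tier == "hom2"] == 1))
  expect_true(all(h[!is.na(a$tier) & a$tier == "hom1_ref"] == 2))
  expect_true(all(h[!is.na(a$tier) & a$tier == "het_ref"] == 3))
  # homozygous diplotypes exactly at hom3
  hom <- a$status == "resolved" & a$hap1 == a$hap2
  expect_identical(which(hom), which(!is.na(a$tier) & a$tier == "hom3"))
})

test_that("resolve-and-extend can only resolve more dogs, never differently", {
  co <- std_cohort(seed = 33, n = 400, K = 12, fis = 0, alpha = 0.3)
  ph_off <- phase_cohort(co$genotypes)
  ph_on <- phase_cohort(co$genotypes, resolve_and_extend = TRUE)
  off <- resolved_diplotypes(ph_off)
  on <- resolved_diplotypes(ph_on)
  expect_true(all(off$dog_id %in% on$dog_id))
  shared <- merge(off, on, by = "dog_id")
  expect_true(all(shared$hap1.x == shared$hap1.y &
                    shared$hap2.x == shared$hap2.y))
  expect_gte(nrow(ph_on$registry), nrow(ph_off$registry))
})

test_that("registry haplotype counts cover resolved chromosomes exactly", {
  co <- std_cohort(seed = 13, n = 600)
  ph <- phase_cohort(co$genotypes)
  r <- resolved_diplotypes(ph)
  counts <- table(c(r$hap1, r$hap2))
  expect_equal(sum(counts), 2 * nrow(r))
  # every haplotype used in a resolved diplotype is registry-known (flag off)
  expect_true(all(names(counts) %in% ph$registry$haplotype))
})

test_that("EM on an all-homozygous cohort equals observed frequencies at once", {
  truth <- data.frame(
    dog_id = sprintf("d%02d", 1:10), breed = "B",
    hap1 = rep(c(HAP_A, HAP_B, HAP_C), c(5, 3, 2)),
    hap2 = rep(c(HAP_A, HAP_B, HAP_C), c(5, 3, 2)),
    stringsAsFactors = FALSE
  )
  em <- em_phase(project_genotypes(truth))
  expect_equal(sum(em$frequencies), 1)
  expect_equal(unname(em$frequencies[c(HAP_A, HAP_B, HAP_C)]),
               c(0.5, 0.3, 0.2))
})

test_that("EM recovers pool frequencies and increases the likelihood", {
  co <- std_cohort(seed = 77)
  em <- em_phase(co$genotypes)
  expect_true(em$converged)
  expect_true(all(diff(em$loglik) >= -1e-9))
  expect_equal(sum(em$frequencies), 1, tolerance = 1e-12)
  pool <- co$pools[[1]]
  est <- em$frequencies[pool$haplotype]
  est[is.na(est)] <- 0
  expect_true(all(abs(est - pool$freq) < 0.02))
})

test_that("EM posterior modes agree with tiered phasing on resolved dogs", {
  co <- std_cohort(seed = 55)
  ph <- phase_cohort(co$genotypes)
  em <- em_phase(co$genotypes)
  r <- resolved_diplotypes(ph)
  e <- em$diplotypes[match(r$dog_id, em$diplotypes$dog_id), ]
  agreement <- mean(e$hap1 == r$hap1 & e$hap2 == r$hap2)
  expect_gte(agreement, 0.99)
})
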