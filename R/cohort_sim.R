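#' @name cohort_sim
#' @title Synthetic breed-stratified DLA cohort generator
#'
#' @description
#' Generates cohorts with the statistical structure of a breed-stratified
#' DLA survey: per-breed pools of 3-30 three-locus haplotypes with strongly
#' skewed (Dirichlet) frequencies, a roughly 79:21 split between the
#' 88-12-DRB1 and 88-88L-DRB1 haplotype structures, breed sizes of ~10-50
#' dogs, and homozygote excess or deficit controlled by a per-breed
#' inbreeding coefficient. Breeds draw their haplotypes from a shared global
#' pool so that haplotypes are shared across breeds, as real breeds share
#' common DLA haplotypes.
#'
#' Inbreeding model: with probability `max(fis, 0)` a dog's two haplotypes
#' are a single draw from the pool (identical by descent); otherwise two
#' independent draws. Negative `fis` is implemented by rejecting homozygous
#' independent draws with probability `|fis|`; the achievable homozygote
#' deficit is bounded by the rejection scheme, which requires at least two
#' haplotypes in the pool.
NULL

#' Per-breed simulation settings
#'
#' @param name breed name.
#' @param n_dogs number of dogs to simulate (positive integer).
#' @param n_haplotypes number of distinct haplotypes in the breed pool.
#' @param dirichlet_alpha concentration of the symmetric Dirichlet from which
#'   pool frequencies are drawn; small values (< 1) give the strongly skewed
#'   distributions seen in real breeds.
#' @param fis per-breed inbreeding coefficient in \[-1, 1\].
#' @param pool optional explicit pool: a data.frame with columns `haplotype`
#'   and `freq` overriding the drawn pool (used for controlled experiments).
#' @return a list of class `breed_config`.
#' @export
breed_config <- function(name, n_dogs, n_haplotypes,
                         dirichlet_alpha = 0.35, fis = 0, pool = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            n_dogs >= 1, n_haplotypes >= 1,
            dirichlet_alpha > 0, fis >= -1, fis <= 1)
  if (!is.null(pool)) {
    stopifnot(is.data.frame(pool), all(c("haplotype", "freq") %in% names(pool)),
              abs(sum(pool$freq) - 1) < 1e-8)
  }
  structure(list(name = name, n_dogs = as.integer(n_dogs),
                 n_haplotypes = as.integer(n_haplotypes),
                 dirichlet_alpha = dirichlet_alpha, fis = fis, pool = pool),
            class = "breed_config")
}

#' Cohort simulation configuration
#'
#' @param breeds a list of [breed_config()] objects.
#' @param frac_88L share of pool haplotypes carrying the 88L structure
#'   (default 0.21, the share observed in the published survey's recurrent
#'   haplotypes).
#' @param allele_pool_sizes named integer vector with entries `88`, `12`,
#'   `88L`, `DRB1`: number of distinct alleles available per (sub)locus.
#' @param n_global_haplotypes size of the shared global haplotype roster from
#'   which breed pools are drawn; sharing across breeds requires this to be
#'   comfortably larger than any single breed's pool.
#' @param seed root RNG seed; the same config and seed always produce a
#'   byte-identical cohort.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(breeds, frac_88L = 0.21,
                       allele_pool_sizes = c("88" = 30, "12" = 14,
                                             "88L" = 8, "DRB1" = 24),
                       n_global_haplotypes = 80L, seed = 1L) {
  stopifnot(length(breeds) >= 1L,
            all(vapply(breeds, inherits, logical(1), "breed_config")),
            frac_88L >= 0, frac_88L <= 1,
            all(c("88", "12", "88L", "DRB1") %in% names(allele_pool_sizes)),
            all(allele_pool_sizes >= 1))
  names(breeds) <- vapply(breeds, `[[`, character(1), "name")
  if (anyDuplicated(names(breeds))) {
    stop("duplicate breed names in config", call. = FALSE)
  }
  structure(list(breeds = breeds, frac_88L = frac_88L,
                 allele_pool_sizes = allele_pool_sizes,
                 n_global_haplotypes = as.integer(n_global_haplotypes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default survey-scale configuration
#'
#' Twenty-four breeds whose sizes, pool sizes and inbreeding coefficients
#' mirror the per-breed scale reported in large DLA surveys (10-49 assigned
#' dogs per breed, 3-27 haplotypes per breed, Fis between about -0.21 and
#' 0.32), with strongly skewed haplotype frequencies.
#'
#' @param seed root RNG seed.
#' @param dirichlet_alpha Dirichlet concentration shared by all breeds.
#' @return a [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, dirichlet_alpha = 0.35) {
  n_dogs <- c(35L, 20L, 32L, 18L, 37L, 39L, 24L, 28L, 12L, 11L, 38L, 12L,
              37L, 10L, 38L, 31L, 29L, 41L, 21L, 26L, 49L, 19L, 39L, 44L)
  n_haps <- c(3L, 5L, 9L, 6L, 11L, 11L, 9L, 12L, 6L, 7L, 10L, 8L,
              13L, 7L, 15L, 9L, 17L, 13L, 11L, 13L, 15L, 12L, 20L, 27L)
  fis <- c(0.315, 0.077, -0.21, 0.020, 0.069, 0.006, 0.171, 0.209,
           -0.038, 0.006, 0.102, 0.245, 0.051, 0.040, 0.003, 0.015,
           -0.03, -0.096, 0.061, 0.066, -0.018, 0.121, -0.022, 0.031)
  breeds <- mapply(function(i, n, k, f) {
    breed_config(sprintf("Breed%02d", i), n, k,
                 dirichlet_alpha = dirichlet_alpha, fis = f)
  }, seq_along(n_dogs), n_dogs, n_haps, fis, SIMPLIFY = FALSE)
  sim_config(breeds, seed = seed)
}

# Deterministic global allele roster for one (sub)locus: distinct full-
# resolution names where consecutive indices share a field-1 group, so that
# field-1 collapsing genuinely merges alleles downstream.
locus_allele_roster <- function(locus, n) {
  i <- seq_len(n)
  sprintf("%s*%03d:%02d", locus, (i + 1L) %/% 2L, ((i - 1L) %% 2L) + 1L)
}

#' Build the shared global haplotype roster
#'
#' Draws `n_global_haplotypes` distinct haplotypes, split between the two
#' structures by `frac_88L`, from the per-locus allele rosters. Deterministic
#' given the config seed.
#'
#' @param cfg a [sim_config()].
#' @return a data.frame with columns `haplotype` and `structure`.
#' @export
build_global_pool <- function(cfg) {
  sizes <- cfg$allele_pool_sizes
  n88L <- floor(cfg$frac_88L * cfg$n_global_haplotypes)
  n12 <- cfg$n_global_haplotypes - n88L
  cap12 <- sizes[["88"]] * sizes[["12"]] * sizes[["DRB1"]]
  cap88L <- sizes[["88"]] * sizes[["88L"]] * sizes[["DRB1"]]
  if (n12 > cap12 || n88L > cap88L) {
    stop("infeasible pool request: global roster larger than the number of ",
         "distinct allele combinations", call. = FALSE)
  }
  draw_structure <- function(n_draw, mid_locus, cap, rng_key) {
    if (n_draw == 0L) {
      return(character(0))
    }
    a88 <- locus_allele_roster("88", sizes[["88"]])
    mid <- locus_allele_roster(mid_locus, sizes[[mid_locus]])
    drb <- locus_allele_roster("DRB1", sizes[["DRB1"]])
    withr_seed <- derive_seed(cfg$seed, paste0("global-pool-", rng_key))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(withr_seed)
    idx <- sample.int(cap, n_draw)                   # distinct triples
    i88 <- ((idx - 1L) %% length(a88)) + 1L
    imid <- (((idx - 1L) %/% length(a88)) %% length(mid)) + 1L
    idrb <- ((idx - 1L) %/% (length(a88) * length(mid))) + 1L
    make_haplotype(a88[i88], mid[imid], drb[idrb])
  }
  h12 <- draw_structure(n12, "12", cap12, "12")
  h88L <- draw_structure(n88L, "88L", cap88L, "88L")
  data.frame(
    haplotype = c(h12, h88L),
    structure = c(rep("88-12-DRB1", n12), rep("88-88L-DRB1", n88L)),
    stringsAsFactors = FALSE
  )
}

# save/restore of the global RNG state so simulation never perturbs the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build one breed's haplotype pool
#'
#' Samples the breed's haplotypes from the global roster (respecting the
#' 88L share: `floor(frac_88L * n_haplotypes)` of the pool carry the 88L
#' structure) and draws their frequencies from a symmetric
#' Dirichlet(`dirichlet_alpha`).
#'
#' @param cfg a [sim_config()].
#' @param breed name of the breed within `cfg`.
#' @param global_pool optional precomputed [build_global_pool()] result.
#' @return a data.frame with columns `haplotype`, `structure`, `freq`.
#' @export
build_breed_pool <- function(cfg, breed, global_pool = NULL) {
  bc <- cfg$breeds[[breed]]
  if (is.null(bc)) stop("unknown breed: ", breed, call. = FALSE)
  if (!is.null(bc$pool)) {
    pool <- bc$pool
    pool$structure <- haplotype_structure(pool$haplotype)
    return(pool[, c("haplotype", "structure", "freq")])
  }
  if (is.null(global_pool)) global_pool <- build_global_pool(cfg)
  k <- bc$n_haplotypes
  k88L <- floor(cfg$frac_88L * k)
  k12 <- k - k88L
  is88L <- global_pool$structure == "88-88L-DRB1"
  if (k12 > sum(!is88L) || k88L > sum(is88L)) {
    stop("infeasible pool request for breed ", breed,
         ": not enough global haplotypes of the required structure",
         call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, paste0("breed-pool-", breed)))
  haps <- c(
    sample(global_pool$haplotype[!is88L], k12),
    if (k88L > 0L) sample(global_pool$haplotype[is88L], k88L) else character(0)
  )
  freq <- stats::rgamma(k, shape = bc$dirichlet_alpha, rate = 1)
  # guard against a degenerate all-zero gamma draw at tiny alpha
  if (sum(freq) <= 0) freq <- rep(1, k)
  freq <- freq / sum(freq)
  data.frame(haplotype = haps,
             structure = haplotype_structure(haps),
             freq = freq, stringsAsFactors = FALSE)
}

# Draw n diplotypes (index pairs into pool) under the IBD-mixture /
# rejection inbreeding model.
draw_diplotypes <- function(n, freq, fis) {
  k <- length(freq)
  if (fis < 0 && k < 2L) {
    stop("config error: negative fis requires at least two haplotypes ",
         "in the pool", call. = FALSE)
  }
  h1 <- integer(n); h2 <- integer(n)
  ibd <- stats::runif(n) < max(fis, 0)
  n_ibd <- sum(ibd)
  if (n_ibd > 0L) {
    h <- sample.int(k, n_ibd, replace = TRUE, prob = freq)
    h1[ibd] <- h; h2[ibd] <- h
  }
  todo <- which(!ibd)
  while (length(todo) > 0L) {
    a <- sample.int(k, length(todo), replace = TRUE, prob = freq)
    b <- sample.int(k, length(todo), replace = TRUE, prob = freq)
    keep <- if (fis < 0) {
      a != b | stats::runif(length(todo)) >= -fis
    } else {
      rep(TRUE, length(todo))
    }
    h1[todo[keep]] <- a[keep]; h2[todo[keep]] <- b[keep]
    todo <- todo[!keep]
  }
  cbind(h1, h2)
}

#' Simulate a breed-stratified cohort
#'
#' For every dog the two true haplotypes are retained (ground truth) and the
#' unphased genotype table is obtained by projecting the diplotype onto
#' per-locus unordered allele pairs.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `true_cohort` with elements `truth` (data.frame:
#'   `dog_id`, `breed`, `hap1`, `hap2`, canonical pair order), `genotypes`
#'   (the unphased genotype table, see [read_genotypes()] for the column
#'   layout), and `pools` (per-breed pool data.frames).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  global_pool <- build_global_pool(cfg)
  truth_list <- vector("list", length(cfg$breeds))
  pools <- vector("list", length(cfg$breeds))
  names(pools) <- names(cfg$breeds)
  dog_counter <- 0L
  for (bi in seq_along(cfg$breeds)) {
    bc <- cfg$breeds[[bi]]
    pool <- build_breed_pool(cfg, bc$name, global_pool)
    pools[[bi]] <- pool
    old <- .Random.seed_save()
    set.seed(derive_seed(cfg$seed, paste0("breed-dogs-", bc$name)))
    idx <- draw_diplotypes(bc$n_dogs, pool$freq, bc$fis)
    .Random.seed_restore(old)
    pair <- canonical_pair(pool$haplotype[idx[, 1]], pool$haplotype[idx[, 2]])
    truth_list[[bi]] <- data.frame(
      dog_id = sprintf("dog%05d", dog_counter + seq_len(bc$n_dogs)),
      breed = bc$name,
      hap1 = pair[, "hap1"],
      hap2 = pair[, "hap2"],
      stringsAsFactors = FALSE
    )
    dog_counter <- dog_counter + bc$n_dogs
  }
  truth <- do.call(rbind, truth_list)
  structure(list(truth = truth,
                 genotypes = project_genotypes(truth),
                 pools = pools),
            class = "true_cohort")
}

#' Project true diplotypes onto an unphased genotype table
#'
#' @param truth data.frame with columns `dog_id`, `breed`, `hap1`, `hap2`.
#' @return genotype data.frame with columns `dog_id`, `breed`, `a88_1`,
#'   `a88_2`, `a12_88L_1`, `a12_88L_2`, `drb1_1`, `drb1_2`; each per-locus
#'   pair in canonical sorted order.
#' @export
project_genotypes <- function(truth) {
  s1 <- split_haplotype(truth$hap1)
  s2 <- split_haplotype(truth$hap2)
  p88 <- canonical_allele_pair(s1$a88, s2$a88)
  p12 <- canonical_allele_pair(s1$a12_88L, s2$a12_88L)
  pdr <- canonical_allele_pair(s1$drb1, s2$drb1)
  data.frame(
    dog_id = truth$dog_id, breed = truth$breed,
    a88_1 = p88[, 1], a88_2 = p88[, 2],
    a12_88L_1 = p12[, 1], a12_88L_2 = p12[, 2],
    drb1_1 = pdr[, 1], drb1_2 = pdr[, 2],
    stringsAsFactors = FALSE
  )
}
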