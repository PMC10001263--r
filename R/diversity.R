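#' @name diversity
#' @title Haplotype frequency tables and diversity statistics
#'
#' @description
#' Frequency tables count haplotype copies over the chromosomes of dogs with
#' an assigned diplotype (2 per dog). Diversity statistics treat the
#' three-locus haplotype as a single multi-allelic marker: observed
#' heterozygosity is the fraction of dogs with two different haplotypes,
#' expected heterozygosity is the Hardy-Weinberg heterozygote probability
#' under the observed haplotype frequencies, the inbreeding coefficient
#' measures homozygote excess, and rarefied haplotype richness is the
#' expected number of distinct haplotypes in a fixed-size subsample of gene
#' copies.
NULL

# accepts a phasing result or a plain diplotype data.frame (hap1, hap2)
as_diplotypes <- function(x) {
  if (inherits(x, "dla_phasing")) {
    return(resolved_diplotypes(x))
  }
  stopifnot(is.data.frame(x), all(c("hap1", "hap2") %in% names(x)))
  x
}

#' Haplotype frequency table
#'
#' Counts each haplotype's copies over the `2 * n_dogs_assigned` chromosomes
#' of dogs with a resolved diplotype. Haplotypes seen exactly once are
#' flagged as singletons; entries with `count < min_count` are flagged as
#' not retained (`min_count = 2` reproduces the convention of reporting only
#' recurrent haplotypes). The split of copies between the 88-12-DRB1 and
#' 88-88L-DRB1 structures is computed over the retained set.
#'
#' @param result a [phase_cohort()] result or a data.frame of diplotypes
#'   (`hap1`, `hap2`, optionally `dog_id`, `breed`).
#' @param min_count minimum copy count for an entry to be retained
#'   (default 2).
#' @return a list of class `hap_table`: `entries` (data.frame `haplotype`,
#'   `structure`, `count`, `frequency`, `n_dogs_with`, `n_homozygous_dogs`,
#'   `singleton`, `retained`), `n_dogs_assigned`, `structure_split`
#'   (data.frame over the retained set with copy counts and percentages per
#'   structure), `min_count`.
#' @export
build_haplotype_table <- function(result, min_count = 2L) {
  dip <- as_diplotypes(result)
  if (nrow(dip) == 0L) stop("zero resolved dogs", call. = FALSE)
  n_assigned <- nrow(dip)
  copies <- c(dip$hap1, dip$hap2)
  haps <- sort_haplotypes(unique(copies))
  count <- as.integer(table(factor(copies, levels = haps)))
  hom <- dip$hap1 == dip$hap2
  n_dogs_with <- vapply(haps, function(hh) {
    sum(dip$hap1 == hh | dip$hap2 == hh)
  }, integer(1), USE.NAMES = FALSE)
  n_hom_dogs <- vapply(haps, function(hh) {
    sum(hom & dip$hap1 == hh)
  }, integer(1), USE.NAMES = FALSE)
  entries <- data.frame(
    haplotype = haps,
    structure = haplotype_structure(haps),
    count = count,
    frequency = count / (2 * n_assigned),
    n_dogs_with = n_dogs_with,
    n_homozygous_dogs = n_hom_dogs,
    singleton = count == 1L,
    retained = count >= min_count,
    stringsAsFactors = FALSE
  )
  entries <- entries[order(-entries$count, haplotype_sort_key(entries$haplotype),
                           method = "radix"), ]
  rownames(entries) <- NULL
  kept <- entries[entries$retained, ]
  split_counts <- vapply(c("88-12-DRB1", "88-88L-DRB1"), function(st) {
    sum(kept$count[kept$structure == st])
  }, integer(1))
  structure_split <- data.frame(
    structure = names(split_counts),
    copies = as.integer(split_counts),
    pct = if (sum(split_counts) > 0) {
      percent(split_counts / sum(split_counts))
    } else {
      rep(NA_real_, 2)
    },
    stringsAsFactors = FALSE
  )
  structure(list(entries = entries,
                 n_dogs_assigned = n_assigned,
                 structure_split = structure_split,
                 min_count = as.integer(min_count)),
            class = "hap_table")
}

#' @export
print.hap_table <- function(x, ...) {
  cat("Haplotype frequency table:", nrow(x$entries), "haplotypes over",
      2 * x$n_dogs_assigned, "chromosomes (", x$n_dogs_assigned,
      "assigned dogs )\n")
  cat("  singletons:", sum(x$entries$singleton),
      " retained (count >=", x$min_count, "):", sum(x$entries$retained), "\n")
  print(utils::head(x$entries, 10))
  invisible(x)
}

#' Observed heterozygosity
#'
#' `Ho = 1 - n_homozygous / N`, the fraction of dogs whose two haplotypes
#' differ.
#'
#' @param N number of dogs with an assigned diplotype.
#' @param n_homozygous number of dogs homozygous for a haplotype.
#' @return Ho in \[0, 1\].
#' @export
observed_heterozygosity <- function(N, n_homozygous) {
  stopifnot(length(N) == length(n_homozygous))
  if (any(N <= 0)) stop("N must be positive", call. = FALSE)
  if (any(n_homozygous < 0 | n_homozygous > N)) {
    stop("n_homozygous must be between 0 and N", call. = FALSE)
  }
  1 - n_homozygous / N
}

#' Expected heterozygosity (gene diversity)
#'
#' Biased estimator `1 - sum(p^2)`; unbiased (Nei small-sample corrected)
#' estimator `(2N / (2N - 1)) * (1 - sum(p^2))`.
#'
#' @param frequencies haplotype frequencies summing to 1.
#' @param N sample size in dogs (required for `mode = "unbiased"`).
#' @param mode `"biased"` (default) or `"unbiased"`.
#' @return He.
#' @export
expected_heterozygosity <- function(frequencies, N = NULL,
                                    mode = c("biased", "unbiased")) {
  mode <- match.arg(mode)
  if (abs(sum(frequencies) - 1) > 1e-8) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  he <- 1 - sum(frequencies^2)
  if (mode == "unbiased") {
    if (is.null(N)) stop("N is required for the unbiased estimator",
                         call. = FALSE)
    he <- (2 * N / (2 * N - 1)) * he
  }
  he
}

#' Inbreeding coefficient Fis
#'
#' `Fis = 1 - Ho / Hs` with `Hs` Nei's unbiased within-sample gene
#' diversity, `Hs = (N / (N - 1)) * (1 - sum(p^2) - Ho / (2N))`. The simpler
#' `1 - Ho / He` with the uncorrected `He = 1 - sum(p^2)` is reported
#' alongside for comparison.
#'
#' @param diplotypes a [phase_cohort()] result or data.frame with `hap1`,
#'   `hap2`.
#' @return a list with `fis` (Nei-Hs based), `fis_simple`, `ho`, `hs`,
#'   `he_biased`, `N`. For a monomorphic cohort all values except `N` are
#'   `NA` (not applicable).
#' @export
inbreeding_fis <- function(diplotypes) {
  dip <- as_diplotypes(diplotypes)
  N <- nrow(dip)
  if (N < 2L) stop("need at least 2 dogs", call. = FALSE)
  copies <- c(dip$hap1, dip$hap2)
  p <- as.vector(table(copies)) / (2 * N)
  if (length(p) < 2L) {
    return(list(fis = NA_real_, fis_simple = NA_real_, ho = NA_real_,
                hs = NA_real_, he_biased = NA_real_, N = N))
  }
  ho <- mean(dip$hap1 != dip$hap2)
  he <- 1 - sum(p^2)
  hs <- (N / (N - 1)) * (he - ho / (2 * N))
  list(fis = 1 - ho / hs,
       fis_simple = 1 - ho / he,
       ho = ho, hs = hs, he_biased = he, N = N)
}

#' Rarefied haplotype richness
#'
#' Expected number of distinct haplotypes in a random subsample of `g` gene
#' copies, computed from exact hypergeometric non-observation probabilities:
#' `Hr(g) = sum_i 1 - choose(2N - N_i, g) / choose(2N, g)`.
#'
#' @param counts integer copy counts per haplotype (summing to 2N).
#' @param g rarefaction sample size in gene copies, `1 <= g <= 2N`.
#' @return Hr(g).
#' @export
haplotype_richness <- function(counts, g) {
  stopifnot(all(counts >= 1), g >= 1)
  total <- sum(counts)
  if (g > total) stop("g must not exceed the total number of gene copies",
                      call. = FALSE)
  miss <- exp(lchoose(total - counts, g) - lchoose(total, g))
  miss[total - counts < g] <- 0       # cannot avoid a haplotype this common
  sum(1 - miss)
}

#' Monte-Carlo Hardy-Weinberg equilibrium test
#'
#' The statistic is the chi-squared discrepancy between observed diplotype
#' counts and their Hardy-Weinberg expectations under the observed haplotype
#' frequencies. The null distribution is generated by randomly re-pairing
#' the `2N` observed chromosomes; `p = (1 + #(null >= observed)) /
#' (1 + n_perm)`. A plain asymptotic chi-squared p-value (df = K(K-1)/2) is
#' reported alongside.
#'
#' @param diplotypes a [phase_cohort()] result or data.frame with `hap1`,
#'   `hap2`.
#' @param n_perm number of Monte-Carlo re-pairings (default 10000).
#' @param seed RNG seed for the re-pairings.
#' @return a list with `p_mc`, `p_asymptotic`, `statistic`, `df`, `n_perm`.
#'   For a monomorphic cohort the p-values are `NA` (not applicable).
#' @export
hwe_test <- function(diplotypes, n_perm = 10000L, seed = 1L) {
  dip <- as_diplotypes(diplotypes)
  N <- nrow(dip)
  if (N < 2L) stop("need at least 2 dogs", call. = FALSE)
  haps <- sort_haplotypes(unique(c(dip$hap1, dip$hap2)))
  K <- length(haps)
  if (K < 2L) {
    return(list(p_mc = NA_real_, p_asymptotic = NA_real_,
                statistic = NA_real_, df = NA_integer_, n_perm = n_perm))
  }
  i1 <- match(dip$hap1, haps)
  i2 <- match(dip$hap2, haps)
  p <- as.vector(table(factor(c(i1, i2), levels = seq_len(K)))) / (2 * N)
  # expected genotype counts under HW; category code for unordered pair
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  code <- (lo - 1L) * K + hi
  pair_lo <- rep(seq_len(K), times = K - seq_len(K) + 1L)
  pair_hi <- unlist(lapply(seq_len(K), function(i) i:K))
  all_codes <- (pair_lo - 1L) * K + pair_hi
  code_index <- integer(K * K)
  code_index[all_codes] <- seq_along(all_codes)
  expected <- ifelse(pair_lo == pair_hi,
                     N * p[pair_lo]^2,
                     2 * N * p[pair_lo] * p[pair_hi])
  keep <- expected > 0
  chi2 <- function(codes) {
    obs <- tabulate(code_index[codes], nbins = length(all_codes))
    sum((obs[keep] - expected[keep])^2 / expected[keep])
  }
  stat <- chi2(code)
  chrom <- c(i1, i2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- sample(chrom)
    a <- perm[seq_len(N)]
    b2 <- perm[N + seq_len(N)]
    codes <- (pmin(a, b2) - 1L) * K + pmax(a, b2)
    if (chi2(codes) >= stat - 1e-12) null_ge <- null_ge + 1L
  }
  df <- K * (K - 1L) / 2L
  list(p_mc = (1 + null_ge) / (1 + n_perm),
       p_asymptotic = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, n_perm = n_perm)
}

#' Per-allele frequency and carrier summary
#'
#' @param genotypes genotype data.frame (see [read_genotypes()]).
#' @return data.frame with `locus_slot` (`88`, `12/88L`, `DRB1`), `allele`,
#'   `count` (copies), `frequency` (copies / 2N), `carriers` (dogs with at
#'   least one copy), `carrier_proportion` (carriers / N).
#' @export
allele_summary <- function(genotypes) {
  stopifnot(nrow(genotypes) >= 1L)
  N <- nrow(genotypes)
  slot_cols <- list("88" = c("a88_1", "a88_2"),
                    "12/88L" = c("a12_88L_1", "a12_88L_2"),
                    "DRB1" = c("drb1_1", "drb1_2"))
  out <- lapply(names(slot_cols), function(slot) {
    c1 <- genotypes[[slot_cols[[slot]][1]]]
    c2 <- genotypes[[slot_cols[[slot]][2]]]
    alleles <- sort_alleles(unique(c(c1, c2)))
    count <- as.integer(table(factor(c(c1, c2), levels = alleles)))
    carriers <- vapply(alleles, function(a) sum(c1 == a | c2 == a),
                       integer(1), USE.NAMES = FALSE)
    data.frame(locus_slot = slot, allele = alleles, count = count,
               frequency = count / (2 * N), carriers = carriers,
               carrier_proportion = carriers / N, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-breed diversity report
#'
#' Computes, for each breed with at least `min_dogs` resolved dogs, the
#' Table-style diversity indices: N (assigned dogs), number of unassigned
#' dogs, number of distinct haplotypes, number of homozygous dogs, observed
#' heterozygosity Ho, expected heterozygosity He (biased and unbiased),
#' inbreeding coefficient Fis (Nei-Hs based and simple), rarefied haplotype
#' richness Hr(g), and the Monte-Carlo HWE p-value.
#'
#' @param result a [phase_cohort()] result.
#' @param min_dogs minimum number of assigned dogs for a breed to be
#'   reported (default 10, the usual survey convention).
#' @param g rarefaction size in gene copies; default `NULL` uses the
#'   smallest `2N` among reported breeds.
#' @param n_perm,seed passed to [hwe_test()].
#' @param exclude breeds to leave out (e.g. mongrels); default none.
#' @return data.frame with one row per breed plus significance flags
#'   (`p < 0.05`, `p < 0.001`; no multiple-testing correction).
#' @export
diversity_report <- function(result, min_dogs = 10L, g = NULL,
                             n_perm = 10000L, seed = 1L,
                             exclude = character(0)) {
  dip <- as_diplotypes(result)
  a <- if (inherits(result, "dla_phasing")) result$assignments else dip
  unassigned <- if (inherits(result, "dla_phasing")) {
    tapply(a$status == "unresolved", a$breed, sum)
  } else {
    NULL
  }
  dip <- dip[!dip$breed %in% exclude, ]
  sizes <- table(dip$breed)
  breeds <- names(sizes)[sizes >= min_dogs]
  if (length(breeds) == 0L) stop("no breed reaches min_dogs", call. = FALSE)
  if (is.null(g)) g <- 2L * min(sizes[breeds])
  rows <- lapply(breeds, function(b) {
    d <- dip[dip$breed == b, ]
    N <- nrow(d)
    counts <- as.vector(table(c(d$hap1, d$hap2)))
    n_hom <- sum(d$hap1 == d$hap2)
    fis <- inbreeding_fis(d)
    hwe <- if (length(counts) >= 2L) {
      hwe_test(d, n_perm = n_perm, seed = derive_seed(seed, b))
    } else {
      list(p_mc = NA_real_, p_asymptotic = NA_real_)
    }
    p <- counts / sum(counts)
    data.frame(
      breed = b,
      N = N,
      n_unassigned = if (is.null(unassigned) || is.na(unassigned[b]))
                       NA_integer_ else as.integer(unassigned[b]),
      n_haplotypes = length(counts),
      n_homozygous = n_hom,
      Ho = observed_heterozygosity(N, n_hom),
      He_biased = expected_heterozygosity(p),
      He_unbiased = expected_heterozygosity(p, N, mode = "unbiased"),
      Fis = fis$fis,
      Fis_simple = fis$fis_simple,
      Hr = haplotype_richness(counts, min(g, 2L * N)),
      hwe_p = hwe$p_mc,
      hwe_p_asymptotic = hwe$p_asymptotic,
      stringsAsFactors = FALSE
    )
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$Hr), ]
  rownames(rep) <- NULL
  rep$sig_0.05 <- !is.na(rep$hwe_p) & rep$hwe_p < 0.05
  rep$sig_0.001 <- !is.na(rep$hwe_p) & rep$hwe_p < 0.001
  rep
}

#' Cohort-level summary of per-breed reports
#'
#' @param reports a [diversity_report()] data.frame.
#' @return a list with `mean_ho` (unweighted arithmetic mean of per-breed
#'   Ho, also given rounded to 3 decimals as `mean_ho_3dp`), `n_breeds`, and
#'   the per-breed table.
#' @export
cohort_summary <- function(reports) {
  stopifnot(nrow(reports) >= 1L, "Ho" %in% names(reports))
  m <- mean(reports$Ho)
  list(mean_ho = m,
       mean_ho_3dp = round_half_up(m, 3),
       n_breeds = nrow(reports),
       per_breed = reports)
}
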