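#' @name matching
#' @title Homozygous-donor haplotype banks and recipient coverage
#'
#' @description
#' Models MHC-matched somatic stem-cell transplantation: donor cell lines
#' are assumed to be derived from dogs homozygous for a three-locus DLA
#' haplotype, and a recipient is considered eligible (covered) when its
#' diplotype carries at least one haplotype present in the donor bank —
#' matching in the host-versus-graft direction only. Donor haplotypes are
#' ranked by their cohort-wide frequency and coverage is accumulated down
#' the ranking.
NULL

#' Rank candidate donor haplotypes
#'
#' Haplotypes observed in at least one homozygous dog, sorted by descending
#' cohort frequency; frequency ties are broken by the canonical haplotype
#' label order, so the ranking is deterministic.
#'
#' @param result a [phase_cohort()] result or diplotype data.frame.
#' @return character vector of donor haplotypes (possibly empty, with a
#'   warning, when the cohort has no homozygote).
#' @export
rank_donor_haplotypes <- function(result) {
  dip <- as_diplotypes(result)
  hom_haps <- unique(dip$hap1[dip$hap1 == dip$hap2])
  if (length(hom_haps) == 0L) {
    warning("no homozygous dog in the cohort; empty donor list")
    return(character(0))
  }
  copies <- c(dip$hap1, dip$hap2)
  count <- vapply(hom_haps, function(hh) sum(copies == hh), integer(1),
                  USE.NAMES = FALSE)
  hom_haps[order(-count, haplotype_sort_key(hom_haps), method = "radix")]
}

#' Cumulative donor coverage curve
#'
#' A dog is matched at rank `k` when its diplotype contains at least one of
#' the top-`k` donor haplotypes. Percentages are over the dogs with an
#' assigned diplotype by default; `denominator` allows the full-cohort count
#' instead.
#'
#' @param result a [phase_cohort()] result or diplotype data.frame.
#' @param donors ordered donor haplotypes (default
#'   [rank_donor_haplotypes()]); must all be observed in the cohort.
#' @param denominator number of dogs used for percentages; default the
#'   number of assigned dogs.
#' @return a data.frame of class `coverage_curve`: `rank`, `haplotype`,
#'   `cum_matched` (dogs), `cum_pct`.
#' @export
coverage_curve <- function(result, donors = NULL, denominator = NULL) {
  dip <- as_diplotypes(result)
  if (nrow(dip) == 0L) stop("no resolved dogs in cohort", call. = FALSE)
  if (is.null(donors)) donors <- rank_donor_haplotypes(result)
  observed <- unique(c(dip$hap1, dip$hap2))
  if (!all(donors %in% observed)) {
    stop("donors must be haplotypes observed in the cohort", call. = FALSE)
  }
  denom <- denominator %||% nrow(dip)
  matched <- rep(FALSE, nrow(dip))
  cum <- integer(length(donors))
  for (k in seq_along(donors)) {
    matched <- matched | dip$hap1 == donors[k] | dip$hap2 == donors[k]
    cum[k] <- sum(matched)
  }
  out <- data.frame(rank = seq_along(donors), haplotype = donors,
                    cum_matched = cum, cum_pct = percent(cum / denom),
                    stringsAsFactors = FALSE)
  class(out) <- c("coverage_curve", "data.frame")
  attr(out, "denominator") <- denom
  out
}

#' Per-breed coverage by the breed's top haplotype
#'
#' For each breed, the most frequent haplotype within the breed (copy-count
#' ties broken by canonical label order) and the fraction of the breed's
#' assigned dogs carrying at least one copy of it.
#'
#' @param result a [phase_cohort()] result or diplotype data.frame.
#' @param min_dogs minimum assigned dogs per breed (default 10).
#' @param exclude breeds to leave out.
#' @return data.frame: `breed`, `top_haplotype`, `carriers`, `N`, `pct`
#'   (one decimal, half-up), sorted by descending `pct`.
#' @export
breed_top_coverage <- function(result, min_dogs = 10L,
                               exclude = character(0)) {
  dip <- as_diplotypes(result)
  dip <- dip[!dip$breed %in% exclude, ]
  sizes <- table(dip$breed)
  breeds <- names(sizes)[sizes >= min_dogs]
  if (length(breeds) == 0L) stop("no breed reaches min_dogs", call. = FALSE)
  rows <- lapply(breeds, function(b) {
    d <- dip[dip$breed == b, ]
    copies <- c(d$hap1, d$hap2)
    haps <- unique(copies)
    count <- vapply(haps, function(hh) sum(copies == hh), integer(1),
                    USE.NAMES = FALSE)
    top <- haps[order(-count, haplotype_sort_key(haps), method = "radix")][1]
    carriers <- sum(d$hap1 == top | d$hap2 == top)
    data.frame(breed = b, top_haplotype = top, carriers = carriers,
               N = nrow(d), pct = percent(carriers / nrow(d)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pct, out$breed, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Breed spread and predominance of each haplotype
#'
#' For each haplotype of a frequency table: the number of distinct breeds
#' (mongrels excluded) in which it was observed, and, when a single breed
#' holds more than 70% of its copies, that predominant breed with its copy
#' share (percent, one decimal).
#'
#' @param table a [build_haplotype_table()] result.
#' @param result the [phase_cohort()] result (or diplotype data.frame) the
#'   table was built from; must carry breed labels.
#' @param mongrel breed label(s) treated as mongrel/mixed and excluded from
#'   breed counts (default `"Mongrel"`).
#' @param threshold predominance threshold on the copy share (default 0.7).
#' @return data.frame: `haplotype`, `n_breeds`, `predominant_breed` (`NA`
#'   when no breed exceeds the threshold), `predominant_pct`.
#' @export
breed_spread <- function(table, result, mongrel = "Mongrel",
                         threshold = 0.7) {
  dip <- as_diplotypes(result)
  stopifnot("breed" %in% names(dip))
  haps <- table$entries$haplotype
  long <- data.frame(breed = rep(dip$breed, 2L),
                     hap = c(dip$hap1, dip$hap2),
                     stringsAsFactors = FALSE)
  pure <- long[!long$breed %in% mongrel, ]
  rows <- lapply(haps, function(hh) {
    hb <- pure$breed[pure$hap == hh]
    tab <- sort(table(hb), decreasing = TRUE)
    share <- if (length(tab) > 0L) tab[1] / sum(tab) else NA_real_
    pred <- length(tab) > 0L && share > threshold
    data.frame(haplotype = hh,
               n_breeds = length(tab),
               predominant_breed = if (pred) names(tab)[1] else NA_character_,
               predominant_pct = if (pred) percent(as.numeric(share))
                                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
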