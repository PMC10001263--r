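#' @name phasing
#' @title Tiered homozygote-anchored haplotype phasing
#'
#' @description
#' Three-locus haplotypes are reconstructed from unphased genotypes in two
#' passes. Dogs homozygous at all three loci, or heterozygous at exactly one
#' locus, have a unique phase; their haplotypes are identified directly and
#' seed a registry of known haplotypes. Remaining dogs are then resolved
#' against the registry: a dog is assigned the unique phase-consistent
#' diplotype whose two haplotypes are both already known; dogs with zero or
#' several registry-consistent candidates stay unresolved. An
#' expectation-maximisation (gene-counting) phaser over the same candidate
#' space serves as an independent maximum-likelihood cross-check.
#'
#' Tiers record how a dog was resolved: `hom3` (homozygous at all three
#' loci), `hom2` (heterozygous at one locus, i.e. homozygous at two),
#' `hom1_ref` (heterozygous at two loci, resolved against the registry),
#' `het_ref` (heterozygous at all three, resolved against the registry).
NULL

#' Enumerate phase-consistent diplotypes of one genotype
#'
#' With `h` heterozygous loci there are `2^max(h - 1, 0)` distinct unordered
#' diplotypes consistent with the genotype (the orientation of the first
#' heterozygous locus is fixed; unordered pairs absorb the global swap).
#'
#' @param g a one-row genotype data.frame (columns as in [read_genotypes()]).
#' @return a data.frame with columns `hap1`, `hap2` (canonical pair order),
#'   one row per candidate diplotype.
#' @export
enumerate_diplotypes <- function(g) {
  cc <- enumerate_all(g)[[1]]
  data.frame(hap1 = cc$hap1, hap2 = cc$hap2, stringsAsFactors = FALSE)
}

# number of heterozygous loci per genotype row, vectorised
n_het_loci <- function(genotypes) {
  (genotypes$a88_1 != genotypes$a88_2) +
    (genotypes$a12_88L_1 != genotypes$a12_88L_2) +
    (genotypes$drb1_1 != genotypes$drb1_2)
}

# Candidate diplotype lists for every dog. The orientation of the first
# heterozygous locus is fixed, the remaining heterozygous loci are swapped
# over all 2^(h-1) bit patterns, and the resulting unordered pairs are
# canonicalised in one vectorised pass over the whole cohort.
enumerate_all <- function(genotypes) {
  n <- nrow(genotypes)
  c1 <- cbind(genotypes$a88_1, genotypes$a12_88L_1, genotypes$drb1_1)
  c2 <- cbind(genotypes$a88_2, genotypes$a12_88L_2, genotypes$drb1_2)
  het <- c1 != c2
  raw1 <- vector("list", n)
  raw2 <- vector("list", n)
  for (i in seq_len(n)) {
    het_idx <- which(het[i, ])
    h <- length(het_idx)
    n_cand <- 2L^max(h - 1L, 0L)
    a1m <- matrix(c1[i, ], nrow = n_cand, ncol = 3L, byrow = TRUE)
    a2m <- matrix(c2[i, ], nrow = n_cand, ncol = 3L, byrow = TRUE)
    vary <- if (h >= 2L) het_idx[-1L] else integer(0)
    for (j in seq_along(vary)) {
      swap <- bitwAnd(seq_len(n_cand) - 1L, bitwShiftL(1L, j - 1L)) != 0L
      l <- vary[j]
      tmp <- a1m[swap, l]
      a1m[swap, l] <- a2m[swap, l]
      a2m[swap, l] <- tmp
    }
    raw1[[i]] <- paste(a1m[, 1], a1m[, 2], a1m[, 3], sep = "|")
    raw2[[i]] <- paste(a2m[, 1], a2m[, 2], a2m[, 3], sep = "|")
  }
  lens <- lengths(raw1)
  pair <- canonical_pair(unlist(raw1), unlist(raw2))
  stop_at <- cumsum(lens)
  start_at <- stop_at - lens + 1L
  lapply(seq_len(n), function(i) {
    ix <- start_at[i]:stop_at[i]
    list(hap1 = pair[ix, "hap1"], hap2 = pair[ix, "hap2"])
  })
}

#' Phase a cohort by tiered homozygote anchoring
#'
#' Pass 1 resolves every dog with at most one heterozygous locus (unique
#' phase) and enters its haplotype(s) into the registry with the tier at
#' which they were first seen. Pass 2 iterates over the still-unresolved
#' dogs (in input order, up to `max_rounds` rounds or until no dog changes
#' status): a dog is resolved if exactly one of its candidate diplotypes has
#' both haplotypes in the registry. Ties (several fully registry-consistent
#' candidates) are never broken by frequency; such dogs stay unresolved and
#' their candidate counts are reported.
#'
#' @param genotypes genotype data.frame (see [read_genotypes()]).
#' @param max_rounds maximum number of pass-2 rounds (default 10). With
#'   `resolve_and_extend = FALSE` the registry is fixed after pass 1 and a
#'   single round reaches the fixpoint.
#' @param resolve_and_extend if `TRUE`, both haplotypes of a dog resolved in
#'   pass 2 join the registry, so later rounds can resolve against
#'   haplotypes first inferred in heterozygous dogs. Default `FALSE`: the
#'   registry contains only haplotypes identified in homozygote-containing
#'   dogs.
#' @return a list of class `dla_phasing`: `assignments` (data.frame with
#'   `dog_id`, `breed`, `status`, `tier`, `hap1`, `hap2`, `n_candidates`
#'   enumerated and `n_consistent` registry-consistent at the final round),
#'   `registry` (data.frame `haplotype`, `structure`, `first_tier`),
#'   `tier_counts`, and the flags used.
#' @export
phase_cohort <- function(genotypes, max_rounds = 10L,
                         resolve_and_extend = FALSE) {
  if (is.null(genotypes) || nrow(genotypes) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  n <- nrow(genotypes)
  cands <- enumerate_all(genotypes)
  h <- n_het_loci(genotypes)
  status <- rep("unresolved", n)
  tier <- rep(NA_character_, n)
  hap1 <- rep(NA_character_, n)
  hap2 <- rep(NA_character_, n)
  n_consistent <- rep(NA_integer_, n)

  registry <- character(0)
  registry_tier <- character(0)
  add_to_registry <- function(haps, tr) {
    new <- setdiff(unique(haps), registry)
    if (length(new) > 0L) {
      registry <<- c(registry, new)
      registry_tier <<- c(registry_tier, rep(tr, length(new)))
    }
  }

  # pass 1: unique phase
  for (i in seq_len(n)) {
    if (h[i] <= 1L) {
      status[i] <- "resolved"
      tier[i] <- if (h[i] == 0L) "hom3" else "hom2"
      hap1[i] <- cands[[i]]$hap1[1]
      hap2[i] <- cands[[i]]$hap2[1]
      n_consistent[i] <- 1L
      add_to_registry(c(hap1[i], hap2[i]), tier[i])
    }
  }

  # pass 2: registry-consistent unique candidates, to fixpoint
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      if (status[i] != "unresolved") next
      ok <- cands[[i]]$hap1 %in% registry & cands[[i]]$hap2 %in% registry
      n_consistent[i] <- sum(ok)
      if (sum(ok) == 1L) {
        j <- which(ok)
        status[i] <- "resolved"
        tier[i] <- if (h[i] == 2L) "hom1_ref" else "het_ref"
        hap1[i] <- cands[[i]]$hap1[j]
        hap2[i] <- cands[[i]]$hap2[j]
        changed <- TRUE
        if (resolve_and_extend) add_to_registry(c(hap1[i], hap2[i]), tier[i])
      }
    }
    if (!changed) break
  }

  assignments <- data.frame(
    dog_id = genotypes$dog_id,
    breed = genotypes$breed,
    status = status,
    tier = tier,
    hap1 = hap1,
    hap2 = hap2,
    n_candidates = vapply(cands, function(cc) length(cc$hap1), integer(1)),
    n_consistent = n_consistent,
    stringsAsFactors = FALSE
  )
  registry_df <- data.frame(
    haplotype = registry,
    structure = if (length(registry) > 0L) haplotype_structure(registry)
                else character(0),
    first_tier = registry_tier,
    stringsAsFactors = FALSE
  )
  structure(list(
    assignments = assignments,
    registry = registry_df,
    tier_counts = table(factor(tier, levels = c("hom3", "hom2", "hom1_ref",
                                                "het_ref"))),
    n_unresolved = sum(status == "unresolved"),
    resolve_and_extend = resolve_and_extend,
    max_rounds = max_rounds
  ), class = "dla_phasing")
}

#' @export
print.dla_phasing <- function(x, ...) {
  n <- nrow(x$assignments)
  cat("Tiered DLA haplotype phasing of", n, "dogs\n")
  cat("  resolved:", n - x$n_unresolved, " unresolved:", x$n_unresolved, "\n")
  cat("  tiers:", paste(names(x$tier_counts), as.integer(x$tier_counts),
                        sep = "=", collapse = "  "), "\n")
  cat("  registry:", nrow(x$registry), "haplotypes\n")
  invisible(x)
}

#' Resolved diplotypes of a phasing result
#'
#' @param result a [phase_cohort()] result.
#' @return data.frame `dog_id`, `breed`, `hap1`, `hap2` of resolved dogs.
#' @export
resolved_diplotypes <- function(result) {
  a <- result$assignments
  a[a$status == "resolved", c("dog_id", "breed", "hap1", "hap2")]
}

#' Maximum-likelihood haplotype phasing by EM (gene counting)
#'
#' Standard gene-counting EM over the haplotype space spanned by the
#' phase-consistent diplotypes of all dogs: starting from uniform haplotype
#' frequencies, each dog's probability mass is distributed over its
#' candidate diplotypes in proportion to the current Hardy-Weinberg
#' diplotype probabilities, and frequencies are re-estimated from the
#' expected haplotype counts. The log-likelihood is non-decreasing at every
#' iteration (checked).
#'
#' @param genotypes genotype data.frame (see [read_genotypes()]).
#' @param tol convergence tolerance on the log-likelihood change
#'   (default 1e-8).
#' @param max_iter maximum number of iterations (default 1000).
#' @return a list of class `dla_em`: `frequencies` (named vector over the
#'   haplotype space, summing to 1), `diplotypes` (data.frame `dog_id`,
#'   `breed`, `hap1`, `hap2`, `posterior` — the posterior-mode diplotype per
#'   dog), `loglik` (trace), `n_iter`, `converged`.
#' @export
em_phase <- function(genotypes, tol = 1e-8, max_iter = 1000L) {
  if (is.null(genotypes) || nrow(genotypes) == 0L) {
    stop("empty cohort", call. = FALSE)
  }
  n <- nrow(genotypes)
  cands <- enumerate_all(genotypes)
  hap_space <- sort_haplotypes(unique(unlist(
    lapply(cands, function(cc) c(cc$hap1, cc$hap2)))))
  K <- length(hap_space)
  d_c <- rep(seq_len(n), vapply(cands, function(cc) length(cc$hap1), integer(1)))
  i1 <- match(unlist(lapply(cands, `[[`, "hap1")), hap_space)
  i2 <- match(unlist(lapply(cands, `[[`, "hap2")), hap_space)
  mult <- ifelse(i1 == i2, 1, 2)

  p <- rep(1 / K, K)
  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- mult * p[i1] * p[i2]
    denom <- as.vector(rowsum(w, d_c))
    ll <- sum(log(denom))
    if (length(loglik) > 0L && ll < loglik[length(loglik)] - 1e-9) {
      stop("EM log-likelihood decreased; this should be impossible",
           call. = FALSE)
    }
    post <- w / denom[d_c]
    cnt <- as.vector(rowsum(c(post, post),
                            factor(c(i1, i2), levels = seq_len(K))))
    p_new <- cnt / (2 * n)
    done <- length(loglik) > 0L && (ll - loglik[length(loglik)]) < tol
    loglik <- c(loglik, ll)
    p <- p_new
    if (done) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  # posterior-mode diplotype per dog under the final frequencies
  w <- mult * p[i1] * p[i2]
  denom <- as.vector(rowsum(w, d_c))
  post <- w / denom[d_c]
  best <- vapply(split(seq_along(post), d_c),
                 function(ix) ix[which.max(post[ix])], integer(1))
  diplotypes <- data.frame(
    dog_id = genotypes$dog_id,
    breed = genotypes$breed,
    hap1 = hap_space[i1[best]],
    hap2 = hap_space[i2[best]],
    posterior = post[best],
    stringsAsFactors = FALSE
  )
  structure(list(
    frequencies = stats::setNames(p, hap_space),
    diplotypes = diplotypes,
    loglik = loglik,
    n_iter = iter,
    converged = converged
  ), class = "dla_em")
}

#' @export
print.dla_em <- function(x, ...) {
  cat("EM haplotype phasing:", length(x$frequencies), "haplotypes,",
      x$n_iter, "iterations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  final log-likelihood:", x$loglik[length(x$loglik)], "\n")
  invisible(x)
}
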