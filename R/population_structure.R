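#' @name population_structure
#' @title Breed frequency matrices, PCA and cross-cohort correlation
#'
#' @description
#' Breed structure is summarised from within-breed haplotype frequencies at
#' field-1 resolution (alleles collapsed to their first name field, which
#' groups alleles with similar peptide-binding regions). Breeds are the
#' observations of a covariance PCA on the raw frequencies — frequencies
#' share a scale, so columns are centred but not standardised by default.
#' Cross-cohort comparisons of per-allele carrier proportions use the
#' Pearson correlation over the union of alleles seen in either cohort.
NULL

#' Breed-by-haplotype frequency matrix
#'
#' @param result a [phase_cohort()] result or diplotype data.frame with
#'   breed labels.
#' @param breeds breeds to include (default: all with at least one resolved
#'   dog); breeds without resolved dogs are dropped with a warning.
#' @param level `"field1"` (default) collapses haplotypes with
#'   [collapse_haplotype_field1()] before counting; `"full"` keeps full
#'   resolution.
#' @return a numeric matrix, rows = breeds, columns = haplotypes; each row
#'   sums to 1 (frequencies over 2 x the breed's assigned dogs).
#' @export
breed_frequency_matrix <- function(result, breeds = NULL,
                                   level = c("field1", "full")) {
  level <- match.arg(level)
  dip <- as_diplotypes(result)
  stopifnot("breed" %in% names(dip))
  if (is.null(breeds)) breeds <- unique(dip$breed)
  missing <- setdiff(breeds, unique(dip$breed))
  if (length(missing) > 0L) {
    warning("breed(s) without resolved dogs excluded: ",
            paste(missing, collapse = ", "))
    breeds <- setdiff(breeds, missing)
  }
  if (length(breeds) == 0L) stop("no breed with resolved dogs", call. = FALSE)
  dip <- dip[dip$breed %in% breeds, ]
  hap <- c(dip$hap1, dip$hap2)
  if (level == "field1") hap <- collapse_haplotype_field1(hap)
  cols <- sort_haplotypes(unique(hap))
  m <- matrix(0, nrow = length(breeds), ncol = length(cols),
              dimnames = list(breeds, cols))
  breed2 <- rep(dip$breed, 2L)
  tab <- table(factor(breed2, levels = breeds), factor(hap, levels = cols))
  m[] <- as.numeric(tab)
  sweep(m, 1, rowSums(m), "/")
}

#' PCA of breeds on haplotype frequencies
#'
#' Column-centred covariance PCA (no standardisation by default, since
#' frequencies share a scale) via singular value decomposition. A
#' deterministic sign convention is applied: within each component the
#' loading of largest magnitude is made positive.
#'
#' @param m a [breed_frequency_matrix()].
#' @param drop_breeds breeds to remove before the analysis (e.g. outliers
#'   for a re-analysis).
#' @param standardize if `TRUE`, scale columns to unit variance
#'   (zero-variance columns are dropped).
#' @return a list of class `breed_pca`: `coordinates` (breeds x components),
#'   `loadings`, `eigenvalues` (non-negative, non-increasing),
#'   `contribution` (ratios summing to 1 over all components).
#' @export
pca_breeds <- function(m, drop_breeds = NULL, standardize = FALSE) {
  stopifnot(is.matrix(m))
  if (!is.null(drop_breeds)) m <- m[setdiff(rownames(m), drop_breeds), ,
                                    drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 breeds for PCA", call. = FALSE)
  x <- scale(m, center = TRUE, scale = FALSE)
  if (standardize) {
    sdv <- apply(x, 2, stats::sd)
    x <- x[, sdv > 0, drop = FALSE]
    x <- sweep(x, 2, sdv[sdv > 0], "/")
  }
  sv <- svd(x)
  k <- sum(sv$d > sv$d[1] * 1e-12)
  d <- sv$d[seq_len(k)]
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading positive per component
  for (j in seq_len(k)) {
    i_max <- which.max(abs(v[, j]))
    if (v[i_max, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  coords <- u %*% diag(d, k, k)
  dimnames(coords) <- list(rownames(m), paste0("PC", seq_len(k)))
  dimnames(v) <- list(colnames(x), paste0("PC", seq_len(k)))
  eig <- d^2 / (n - 1)
  structure(list(coordinates = coords,
                 loadings = v,
                 eigenvalues = eig,
                 contribution = eig / sum(eig)),
            class = "breed_pca")
}

#' @export
print.breed_pca <- function(x, ...) {
  cat("Breed PCA:", nrow(x$coordinates), "breeds,",
      length(x$eigenvalues), "components\n")
  cat("  contribution ratios:",
      paste0(sprintf("PC%d=%.1f%%", seq_len(min(4, length(x$contribution))),
                     100 * x$contribution[seq_len(min(4, length(x$contribution)))]),
             collapse = "  "), "\n")
  invisible(x)
}

#' Pearson correlation of carrier proportions between two cohorts
#'
#' Computed over the union of alleles observed in either cohort; alleles
#' absent from one cohort enter with proportion 0. Symmetric in its two
#' arguments.
#'
#' @param propsA,propsB named numeric vectors of per-allele carrier
#'   proportions.
#' @return Pearson r, or `NA` (not applicable) when either vector has zero
#'   variance over the union.
#' @export
carrier_correlation <- function(propsA, propsB) {
  stopifnot(!is.null(names(propsA)), !is.null(names(propsB)))
  alleles <- union(names(propsA), names(propsB))
  if (length(alleles) < 3L) {
    stop("need at least 3 alleles in the union", call. = FALSE)
  }
  a <- ifelse(alleles %in% names(propsA), propsA[alleles], 0)
  b <- ifelse(alleles %in% names(propsB), propsB[alleles], 0)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}
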