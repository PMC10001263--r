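#' @name nomenclature
#' @title DLA allele and haplotype nomenclature
#'
#' @description
#' MHC-style allele names are `<locus>*<field1>:<field2>:...` with up to four
#' colon-separated numeric fields, e.g. `88*004:02`, `12*001:01:01`,
#' `DRB1*092:01:1`. Tentative (not yet officially named) alleles carry a
#' single `nov<number>` token instead of numeric fields, e.g. `88*nov65`.
#' The `DLA-` prefix is optional on input. The middle position of a
#' three-locus haplotype is occupied by either DLA-12 or the hybrid locus
#' DLA-88L; the sublocus is carried explicitly in the allele name prefix
#' (`12*` or `88L*`), never inferred, because officially DLA-88L alleles are
#' published under the `DLA-88*` prefix.
#'
#' Three-locus haplotypes are represented as pipe-joined strings, e.g.
#' `"88*004:02|12*001:01:01|DRB1*006:01"`.
NULL

DLA_LOCI <- c("88", "12", "88L", "DRB1")

ALLELE_RE <- "^(?:DLA-)?(88L|88|12|DRB1)\\*((?:[0-9]+(?::[0-9]+)*)|nov[0-9]+)$"

#' Parse DLA allele labels
#'
#' @param labels character vector of allele labels matching the grammar
#'   `[DLA-]<locus>*<fields>` where `<locus>` is one of `88`, `12`, `88L`,
#'   `DRB1` and `<fields>` is 1-4 colon-separated numeric fields or a
#'   `nov<number>` token for tentative alleles.
#' @return a data.frame with one row per label and columns `raw` (input),
#'   `locus`, `fields` (colon-joined field string or the `nov` token),
#'   `tentative` (logical), and `label` (canonical form without the `DLA-`
#'   prefix).
#' @examples
#' parse_allele(c("88*004:02", "DRB1*092:01:1", "88*nov65"))
#' @export
parse_allele <- function(labels) {
  stopifnot(is.character(labels), length(labels) >= 1L)
  m <- regmatches(labels, regexec(ALLELE_RE, labels, perl = TRUE))
  bad <- lengths(m) == 0L
  if (any(bad)) {
    stop("malformed allele label(s): ",
         paste(sQuote(labels[bad]), collapse = ", "),
         call. = FALSE)
  }
  locus <- vapply(m, `[`, character(1), 2L)
  fields <- vapply(m, `[`, character(1), 3L)
  tentative <- startsWith(fields, "nov")
  n_fields <- ifelse(tentative, 1L,
                     lengths(strsplit(fields, ":", fixed = TRUE)))
  if (any(n_fields > 4L)) {
    stop("allele label(s) with more than four fields: ",
         paste(sQuote(labels[n_fields > 4L]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    raw = labels,
    locus = locus,
    fields = fields,
    tentative = tentative,
    label = paste0(locus, "*", fields),
    stringsAsFactors = FALSE
  )
}

#' Test whether labels are valid allele names
#'
#' @inheritParams parse_allele
#' @return logical vector.
#' @export
is_valid_allele <- function(labels) {
  grepl(ALLELE_RE, labels, perl = TRUE) &
    lengths(regmatches(labels, gregexpr(":", labels, fixed = TRUE))) <= 3L
}

#' Format parsed alleles
#'
#' @param alleles a data.frame as returned by [parse_allele()], or a
#'   character vector of labels (parsed on the fly).
#' @param style `"sublocus"` (default) keeps the explicit sublocus prefix so
#'   that formatting round-trips with [parse_allele()]; `"official"` prints
#'   DLA-88L alleles under the `88*` prefix, following the official naming of
#'   88L alleles.
#' @param prefix if `TRUE`, prepend `DLA-`.
#' @return character vector of formatted labels.
#' @export
format_allele <- function(alleles, style = c("sublocus", "official"),
                          prefix = FALSE) {
  style <- match.arg(style)
  if (is.character(alleles)) alleles <- parse_allele(alleles)
  locus <- alleles$locus
  if (style == "official") locus[locus == "88L"] <- "88"
  out <- paste0(locus, "*", alleles$fields)
  if (prefix) out <- paste0("DLA-", out)
  out
}

#' Collapse allele names to field-1 resolution
#'
#' Keeps only the first colon-separated field of each numeric allele name
#' (e.g. `88*001:01:01` -> `88*001`), grouping alleles that share the
#' peptide-binding-region-defining first field. Tentative `nov` alleles have
#' no official field structure and are returned unchanged, as atomic field-1
#' units.
#'
#' Idempotent: collapsing a collapsed name is a no-op.
#'
#' @inheritParams parse_allele
#' @return character vector of field-1 labels.
#' @examples
#' collapse_field1(c("88*001:01:01", "DRB1*015:02", "12*nov18"))
#' @export
collapse_field1 <- function(labels) {
  p <- parse_allele(labels)
  f1 <- ifelse(p$tentative, p$fields,
               sub(":.*$", "", p$fields))
  paste0(p$locus, "*", f1)
}

# Sortable key implementing the canonical strict total order on allele
# names: (locus rank, numeric field values elementwise, shorter prefix
# first, tentative alleles last within locus by nov number). Keys compare
# lexicographically. Computed once per unique label.
allele_sort_key <- function(labels) {
  u <- unique(labels)
  p <- parse_allele(u)
  rank <- match(p$locus, DLA_LOCI)
  body <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    if (p$tentative[i]) {
      num <- as.integer(sub("^nov", "", p$fields[i]))
      body[i] <- sprintf("~%05d", num)          # '~' sorts after digits
    } else {
      f <- as.integer(strsplit(p$fields[i], ":", fixed = TRUE)[[1]])
      body[i] <- paste(sprintf("%05d", f), collapse = ":")
    }
  }
  paste0(rank, "|", body)[match(labels, u)]
}

#' Sort allele labels into canonical order
#'
#' Canonical order is by locus (88, 12, 88L, DRB1), then numeric field
#' values, with tentative `nov` alleles last within a locus. This order
#' defines canonical unordered allele pairs and haplotype pairs.
#'
#' @inheritParams parse_allele
#' @return the labels, sorted.
#' @export
sort_alleles <- function(labels) {
  labels[order(allele_sort_key(labels), method = "radix")]
}

#' Build a three-locus haplotype string
#'
#' @param a88 allele label at DLA-88.
#' @param a12_88L allele label at the DLA-12/88L slot (sublocus prefix `12*`
#'   or `88L*`).
#' @param drb1 allele label at DLA-DRB1.
#' @return character vector of `"88*..|12*..|DRB1*.."` haplotype strings.
#' @export
make_haplotype <- function(a88, a12_88L, drb1) {
  p88 <- parse_allele(a88); p12 <- parse_allele(a12_88L); pd <- parse_allele(drb1)
  if (any(p88$locus != "88")) {
    stop("first haplotype position must be a DLA-88 allele", call. = FALSE)
  }
  if (any(!p12$locus %in% c("12", "88L"))) {
    stop("invalid haplotype: middle allele must be at sublocus 12 or 88L, got ",
         paste(sQuote(unique(p12$locus[!p12$locus %in% c("12", "88L")])),
               collapse = ", "),
         call. = FALSE)
  }
  if (any(pd$locus != "DRB1")) {
    stop("third haplotype position must be a DLA-DRB1 allele", call. = FALSE)
  }
  paste(p88$label, p12$label, pd$label, sep = "|")
}

#' Split haplotype strings into allele labels
#'
#' @param haps character vector of haplotype strings.
#' @return a data.frame with columns `a88`, `a12_88L`, `drb1`.
#' @export
split_haplotype <- function(haps) {
  parts <- strsplit(haps, "|", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("malformed haplotype string(s): ",
         paste(sQuote(haps[lengths(parts) != 3L]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    a88 = vapply(parts, `[`, character(1), 1L),
    a12_88L = vapply(parts, `[`, character(1), 2L),
    drb1 = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
}

#' Haplotype structure (88-12-DRB1 vs 88-88L-DRB1)
#'
#' The middle slot of a three-locus haplotype carries either a DLA-12 or a
#' DLA-88L allele, defining one of the two haplotype structures.
#'
#' @param haps character vector of haplotype strings (see [make_haplotype()]).
#' @return character vector, `"88-12-DRB1"` or `"88-88L-DRB1"`.
#' @export
haplotype_structure <- function(haps) {
  mid <- parse_allele(split_haplotype(haps)$a12_88L)
  if (any(!mid$locus %in% c("12", "88L"))) {
    stop("invalid haplotype: middle allele at locus ",
         paste(sQuote(unique(mid$locus[!mid$locus %in% c("12", "88L")])),
               collapse = ", "),
         " (must be sublocus 12 or 88L)", call. = FALSE)
  }
  ifelse(mid$locus == "12", "88-12-DRB1", "88-88L-DRB1")
}

#' Collapse haplotypes to field-1 resolution
#'
#' Applies [collapse_field1()] to each of the three allele positions.
#'
#' @inheritParams haplotype_structure
#' @return character vector of field-1 haplotype strings.
#' @export
collapse_haplotype_field1 <- function(haps) {
  s <- split_haplotype(haps)
  paste(collapse_field1(s$a88), collapse_field1(s$a12_88L),
        collapse_field1(s$drb1), sep = "|")
}

# Sortable key for whole haplotypes (concatenated allele keys).
haplotype_sort_key <- function(haps) {
  u <- unique(haps)
  s <- split_haplotype(u)
  key_u <- paste(allele_sort_key(s$a88), allele_sort_key(s$a12_88L),
                 allele_sort_key(s$drb1), sep = "||")
  key_u[match(haps, u)]
}

#' Sort haplotype strings into canonical order
#'
#' @inheritParams haplotype_structure
#' @return the haplotypes, sorted by the canonical allele order at each
#'   position.
#' @export
sort_haplotypes <- function(haps) {
  haps[order(haplotype_sort_key(haps), method = "radix")]
}

# Canonical unordered pair: returns a 2-column matrix with the two
# haplotypes of each diplotype in canonical order.
canonical_pair <- function(h1, h2) {
  k1 <- haplotype_sort_key(h1)
  k2 <- haplotype_sort_key(h2)
  swap <- k2 < k1
  cbind(hap1 = ifelse(swap, h2, h1), hap2 = ifelse(swap, h1, h2))
}

# Canonical unordered allele pair (used for per-locus genotype columns).
canonical_allele_pair <- function(a1, a2) {
  k1 <- allele_sort_key(a1)
  k2 <- allele_sort_key(a2)
  swap <- k2 < k1
  cbind(ifelse(swap, a2, a1), ifelse(swap, a1, a2))
}
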