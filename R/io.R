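#' @name io
#' @title File formats and the pipeline driver
#'
#' @description
#' All tables are tab-separated UTF-8 text with Unix newlines. Genotype
#' tables have the header `dog_id, breed, a88_1, a88_2, a12_88L_1,
#' a12_88L_2, drb1_1, drb1_2`; allele tokens follow the nomenclature grammar
#' with an explicit sublocus prefix (`12*` / `88L*` in the middle columns);
#' missing calls are `NA` and must affect both alleles of a pair. Output
#' files carry `#`-prefixed header comments (seed, configuration hash) and
#' are re-parseable by the package's own readers.
NULL

GENOTYPE_COLUMNS <- c("dog_id", "breed", "a88_1", "a88_2",
                      "a12_88L_1", "a12_88L_2", "drb1_1", "drb1_2")

#' Read an unphased genotype table
#'
#' Validates every row (allele grammar, sublocus legal for its column, both
#' alleles of a pair present or both `NA`) with line-number diagnostics,
#' stores each per-locus pair in canonical sorted order, and drops dogs with
#' any missing locus from the returned table with a message.
#'
#' @param path TSV file path.
#' @return genotype data.frame (columns as above, pairs canonically sorted).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, colClasses = "character",
                           na.strings = "NA", comment.char = "#",
                           check.names = FALSE)
  if (!identical(names(raw), GENOTYPE_COLUMNS)) {
    stop("bad genotype header in ", path, ": expected ",
         paste(GENOTYPE_COLUMNS, collapse = ", "), call. = FALSE)
  }
  legal <- list(a88 = "88", a12_88L = c("12", "88L"), drb1 = "DRB1")
  for (slot in names(legal)) {
    c1 <- paste0(slot, "_1"); c2 <- paste0(slot, "_2")
    one_na <- xor(is.na(raw[[c1]]), is.na(raw[[c2]]))
    if (any(one_na)) {
      stop("row ", which(one_na)[1] + 1L, " of ", path,
           ": only one allele of the ", slot, " pair is NA", call. = FALSE)
    }
    for (col in c(c1, c2)) {
      vals <- raw[[col]]
      present <- !is.na(vals)
      ok <- is_valid_allele(vals[present])
      if (!all(ok)) {
        bad_row <- which(present)[!ok][1]
        stop("row ", bad_row + 1L, " of ", path, ": malformed allele ",
             sQuote(vals[present][!ok][1]), " in column ", col, call. = FALSE)
      }
      locus <- parse_allele(vals[present])$locus
      wrong <- !locus %in% legal[[slot]]
      if (any(wrong)) {
        bad_row <- which(present)[wrong][1]
        stop("row ", bad_row + 1L, " of ", path, ": allele ",
             sQuote(vals[present][wrong][1]), " at locus ",
             locus[wrong][1], " is not legal in column ", col, call. = FALSE)
      }
    }
  }
  complete <- stats::complete.cases(raw[, GENOTYPE_COLUMNS[-(1:2)]])
  if (any(!complete)) {
    message(sum(!complete), " dog(s) with a missing locus excluded from ",
            "phasing input")
    raw <- raw[complete, ]
  }
  for (slot in names(legal)) {
    c1 <- paste0(slot, "_1"); c2 <- paste0(slot, "_2")
    pair <- canonical_allele_pair(raw[[c1]], raw[[c2]])
    raw[[c1]] <- pair[, 1]; raw[[c2]] <- pair[, 2]
  }
  rownames(raw) <- NULL
  raw
}

# shared writer: optional '#' comment header then a TSV body
write_tsv <- function(x, path, comments = character(0)) {
  con <- file(path, open = "wb")   # binary mode => Unix newlines everywhere
  on.exit(close(con))
  if (length(comments) > 0L) {
    writeLines(paste0("# ", comments), con, sep = "\n")
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write a genotype table
#'
#' @param genotypes genotype data.frame.
#' @param path output TSV path.
#' @param comments optional character vector written as `#` header lines.
#' @return the path, invisibly.
#' @export
write_genotypes <- function(genotypes, path, comments = character(0)) {
  stopifnot(identical(names(genotypes), GENOTYPE_COLUMNS))
  write_tsv(genotypes, path, comments)
}

#' Read / write a ground-truth diplotype table
#'
#' Ground truth tables have columns `dog_id`, `breed`, `hap1`, `hap2` with
#' pipe-joined haplotype strings.
#'
#' @param truth data.frame with those columns.
#' @param path TSV path.
#' @param comments optional `#` header lines.
#' @return `read_truth`: the data.frame; `write_truth`: the path, invisibly.
#' @export
write_truth <- function(truth, path, comments = character(0)) {
  stopifnot(all(c("dog_id", "breed", "hap1", "hap2") %in% names(truth)))
  write_tsv(truth[, c("dog_id", "breed", "hap1", "hap2")], path, comments)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- utils::read.delim(path, colClasses = "character", comment.char = "#")
  stopifnot(identical(names(x), c("dog_id", "breed", "hap1", "hap2")))
  invisible(split_haplotype(c(x$hap1, x$hap2)))   # validates the grammar
  x
}

#' Read a simulation/run configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) with the [sim_config()] keys:
#' `breeds` (list of `{name, n_dogs, n_haplotypes, dirichlet_alpha, fis}`),
#' `frac_88L`, `allele_pool_sizes`, `n_global_haplotypes`, `seed`.
#'
#' @param path config file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    "json" = jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE),
    "yml" = ,
    "yaml" = yaml::read_yaml(path),
    stop("config must be .json, .yml or .yaml", call. = FALSE)
  )
  breeds <- lapply(cfg$breeds, function(b) {
    breed_config(b$name, b$n_dogs, b$n_haplotypes,
                 dirichlet_alpha = b$dirichlet_alpha %||% 0.35,
                 fis = b$fis %||% 0)
  })
  pool_sizes <- unlist(cfg$allele_pool_sizes %||%
                         list("88" = 30, "12" = 14, "88L" = 8, "DRB1" = 24))
  sim_config(breeds,
             frac_88L = cfg$frac_88L %||% 0.21,
             allele_pool_sizes = pool_sizes,
             n_global_haplotypes = cfg$n_global_haplotypes %||% 80L,
             seed = cfg$seed %||% 1L)
}

# cheap deterministic fingerprint of a configuration for output headers
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  sprintf("%08x", derive_seed(0, as.character(s)))
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a cohort, phase it, and write every stage's table
#' under `outdir` as `<prefix>.<stage>.tsv`: genotypes, truth (simulation
#' only), phasing, registry, haplotypes, diversity, alleles, coverage,
#' breed_coverage, matrix, pca. All outputs carry the seed and a
#' configuration fingerprint as `#` header comments.
#'
#' @param cfg a [sim_config()] (used when `genotypes` is `NULL`).
#' @param genotypes optional genotype data.frame or TSV path; when given,
#'   the simulation stage is skipped.
#' @param outdir output directory (created if needed).
#' @param prefix file-name prefix (default `"run"`).
#' @param min_count singleton filter for the haplotype table (default 2).
#' @param min_dogs per-breed reporting threshold (default 10).
#' @param n_perm HWE permutations (default 10000).
#' @param resolve_and_extend passed to [phase_cohort()].
#' @return invisibly, a list with every stage's in-memory result and the
#'   written file paths.
#' @export
run_pipeline <- function(cfg = default_sim_config(), genotypes = NULL,
                         outdir = ".", prefix = "run", min_count = 2L,
                         min_dogs = 10L, n_perm = 10000L,
                         resolve_and_extend = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(paste0("seed=", cfg$seed), paste0("config=", config_hash(cfg)))
  path <- function(stage) file.path(outdir, paste0(prefix, ".", stage, ".tsv"))
  paths <- character(0)
  out <- list()

  if (is.null(genotypes)) {
    cohort <- simulate_cohort(cfg)
    genotypes <- cohort$genotypes
    write_genotypes(genotypes, path("genotypes"), hdr)
    write_truth(cohort$truth, path("truth"), hdr)
    paths <- c(paths, path("genotypes"), path("truth"))
    out$cohort <- cohort
  } else if (is.character(genotypes)) {
    genotypes <- read_genotypes(genotypes)
  }

  phased <- phase_cohort(genotypes, resolve_and_extend = resolve_and_extend)
  message("phasing tiers: ",
          paste(names(phased$tier_counts), as.integer(phased$tier_counts),
                sep = "=", collapse = " "),
          " unresolved=", phased$n_unresolved)
  write_tsv(phased$assignments, path("phasing"), hdr)
  write_tsv(phased$registry, path("registry"), hdr)

  tab <- build_haplotype_table(phased, min_count = min_count)
  write_tsv(tab$entries, path("haplotypes"), hdr)

  seed_div <- derive_seed(cfg$seed, "diversity")
  div <- diversity_report(phased, min_dogs = min_dogs, n_perm = n_perm,
                          seed = seed_div)
  write_tsv(div, path("diversity"), hdr)

  alleles <- allele_summary(genotypes)
  write_tsv(alleles, path("alleles"), hdr)

  donors <- rank_donor_haplotypes(phased)
  cov <- coverage_curve(phased, donors)
  write_tsv(as.data.frame(cov), path("coverage"), hdr)
  bcov <- breed_top_coverage(phased, min_dogs = min_dogs)
  write_tsv(bcov, path("breed_coverage"), hdr)

  m <- breed_frequency_matrix(phased,
                              breeds = div$breed)
  write_tsv(data.frame(breed = rownames(m), m, check.names = FALSE),
            path("matrix"), hdr)
  pca <- pca_breeds(m)
  coords <- data.frame(breed = rownames(pca$coordinates),
                       pca$coordinates, check.names = FALSE)
  write_tsv(coords, path("pca"), hdr)
  write_tsv(data.frame(component = seq_along(pca$eigenvalues),
                       eigenvalue = pca$eigenvalues,
                       contribution = pca$contribution),
            path("scree"), hdr)

  paths <- c(paths, path("phasing"), path("registry"), path("haplotypes"),
             path("diversity"), path("alleles"), path("coverage"),
             path("breed_coverage"), path("matrix"), path("pca"),
             path("scree"))
  out <- c(out, list(genotypes = genotypes, phased = phased, table = tab,
                     diversity = div, alleles = alleles, donors = donors,
                     coverage = cov, breed_coverage = bcov, matrix = m,
                     pca = pca, paths = paths))
  invisible(out)
}
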