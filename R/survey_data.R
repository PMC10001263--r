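#' Bundled DLA survey summary tables
#'
#' Breed- and cohort-level summary statistics from a published large-scale
#' DLA genotyping survey of 829 dogs of 59 breeds in Japan, in which 803
#' dogs of 49 breeds received a three-locus (DLA-88, DLA-12/88L, DLA-DRB1)
#' haplotype assignment. Only printed summary counts are bundled — the
#' per-dog genotypes are not distributed here; analyses that need
#' individual-level data run on synthetic cohorts from [simulate_cohort()].
#'
#' Available tables:
#' \describe{
#'   \item{`cohort`}{named list of cohort-level counts: dogs, assigned dogs,
#'     phasing-tier counts, recurrent/singleton haplotype counts, the copy
#'     split between the two haplotype structures, and the donor-bank
#'     matching counts at 9/28/52 donor haplotypes.}
#'   \item{`breed_diversity`}{per-breed diversity indices (24 breeds and
#'     mongrels): assigned/unassigned dogs, haplotype and homozygote counts,
#'     published Ho/He/Fis/Hr values and HWE flags.}
#'   \item{`top_haplotypes`}{the 29 most frequent haplotypes with copy
#'     counts, carrier and homozygote counts, breed spread and predominant
#'     breed.}
#'   \item{`breed_top_haplotype`}{each breed's most frequent haplotype with
#'     carrier counts over the breed's genotyped dogs.}
#' }
#'
#' @param name one of `"cohort"`, `"breed_diversity"`, `"top_haplotypes"`,
#'   `"breed_top_haplotype"`.
#' @return a data.frame, or a named list for `"cohort"`.
#' @export
dla_survey <- function(name = c("cohort", "breed_diversity",
                                "top_haplotypes", "breed_top_haplotype")) {
  name <- match.arg(name)
  file <- switch(name,
    cohort = "dla_survey_cohort.json",
    breed_diversity = "dla_survey_breed_diversity.tsv",
    top_haplotypes = "dla_survey_top_haplotypes.tsv",
    breed_top_haplotype = "dla_survey_breed_top_haplotype.tsv"
  )
  path <- system.file("extdata", file, package = "dlahap", mustWork = TRUE)
  if (name == "cohort") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}
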