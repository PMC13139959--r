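#' Published diversity summary of the 23-assay Greyia panel
#'
#' Per-assay genetic diversity statistics of the 23 SNP Type assays applied
#' to 73 wild-growing *Greyia* trees, as published with the panel: sample
#' size `n`, minor allele frequency `maf`, observed heterozygosity `h_o`,
#' unbiased gene diversity `h_s` and polymorphic information content `pic`,
#' overall and within the three species clusters (`_gsu` Sutherlandii,
#' `_gra` Radlkoferi, `_gfl` Flanaganii). The `species` column names the
#' species whose allele each assay targets. Useful as a reference point for
#' validating the diversity statistics and as a realistic panel profile.
#'
#' @return tibble with 23 rows (one per assay).
#' @export
greyia_panel_stats <- function() {
  path <- system.file("extdata", "greyia_panel_diversity.csv",
                      package = "snppanel", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, colClasses = c(assay = "character",
                                                  species = "character")))
}

#' Reconstruct a genotype vector from printed summary statistics
#'
#' Builds a single-locus genotype composition consistent with a published
#' `(n, maf, h_o)` triple: the minor-allele count is `round(maf * 2n)`, the
#' heterozygote count `round(h_o * n)`, and the remaining minor alleles are
#' placed as minor-allele homozygotes. Feeding the result to
#' [locus_summary()] recomputes the published `h_s` and `pic` from first
#' principles.
#'
#' @param n genotyped sample count.
#' @param maf printed minor allele frequency.
#' @param h_o printed observed heterozygosity.
#' @param locus_id name for the reconstructed locus.
#' @return genotype table with `n` samples and one locus.
#' @export
reconstruct_genotypes <- function(n, maf, h_o, locus_id = "locus") {
  m <- round(maf * 2 * n)        # minor allele copies
  het <- round(h_o * n)          # heterozygotes
  hom_minor <- (m - het) / 2
  if (hom_minor != round(hom_minor) || hom_minor < 0 ||
      het + hom_minor > n) {
    stop("inconsistent (n, maf, h_o) triple")
  }
  codes <- c(rep(2L, hom_minor), rep(1L, het),
             rep(0L, n - het - hom_minor))
  mat <- matrix(codes, ncol = 1,
                dimnames = list(sprintf("s%03d", seq_len(n)), locus_id))
  as_geno_tbl(mat)
}
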