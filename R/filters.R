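#' Hard-filter cascade for discovery genotype matrices
#'
#' The cascade mirrors standard RADseq SNP filtering practice: (1) mask
#' individual calls failing depth/quality thresholds, (2) mask heterozygous
#' calls with skewed allele balance, (3) drop loci by minor allele count,
#' (4) drop loci by missingness. `filter_genotypes()` runs all four stages
#' in that order and returns the filtered object plus a per-stage report.
#' All boundary values are inclusive (a call with depth exactly `min_depth`
#' or balance exactly 0.25 is retained).
#'
#' @param x a [snp_geno()] object (stages 1-2 need per-call metadata; when
#'   it is absent they are logged no-ops) or a genotype table.
#' @param min_depth minimum read depth per call (default 10).
#' @param min_gq minimum phred-scaled genotype quality per call (default 30).
#' @param balance_range inclusive allele-balance window, the fraction of a
#'   heterozygote's reads carrying the reference allele (default 0.25-0.75).
#' @param min_mac minimum minor allele count per locus, counted over
#'   non-missing calls after masking (default 2).
#' @param max_missing maximum missing-call fraction per locus (default 0.5).
#' @param per_sample_max_missing optional per-sample missingness cutoff;
#'   samples above it are dropped (default `NULL`, off).
#'
#' @return `filter_genotypes()`: list with `genotypes` (filtered `snp_geno`)
#'   and `report` (tibble: stage, loci in/out, calls masked). The individual
#'   stage functions return the modified `snp_geno`.
#' @export
filter_genotypes <- function(x, min_depth = 10, min_gq = 30,
                             balance_range = c(0.25, 0.75),
                             min_mac = 2, max_missing = 0.5,
                             per_sample_max_missing = NULL) {
  x <- as_snp_geno(x)
  report <- list()
  log_stage <- function(stage, before, after, masked = 0L) {
    tibble::tibble(stage = stage,
                   n_loci_in = ncol(before$geno) - 1L,
                   n_loci_out = ncol(after$geno) - 1L,
                   n_calls_masked = masked)
  }
  before <- x
  x <- mask_low_quality_calls(x, min_depth, min_gq)
  report$quality <- log_stage("quality_mask", before, x,
                              masked_calls(before, x))
  before <- x
  x <- filter_allele_balance(x, balance_range)
  report$balance <- log_stage("allele_balance", before, x,
                              masked_calls(before, x))
  before <- x
  x <- drop_loci(x, locus_mac(x) >= min_mac)
  report$mac <- log_stage("min_mac", before, x)
  before <- x
  x <- drop_loci(x, locus_missingness(x) <= max_missing)
  report$missing <- log_stage("locus_missingness", before, x)
  if (!is.null(per_sample_max_missing)) {
    g <- as_geno_matrix(x)
    keep <- rowMeans(is.na(g)) <= per_sample_max_missing
    x$geno <- x$geno[keep, , drop = FALSE]
    for (m in c("depth", "gq", "ad_ref", "ad_alt")) {
      if (!is.null(x[[m]])) x[[m]] <- x[[m]][keep, , drop = FALSE]
    }
  }
  if (ncol(x$geno) == 1L) warning("no loci survived filtering")
  list(genotypes = x, report = dplyr::bind_rows(report))
}

masked_calls <- function(before, after) {
  sum(is.na(as_geno_matrix(after))) - sum(is.na(as_geno_matrix(before)))
}

#' @rdname filter_genotypes
#' @export
mask_low_quality_calls <- function(x, min_depth = 10, min_gq = 30) {
  x <- as_snp_geno(x)
  if (is.null(x$depth) && is.null(x$gq)) {
    message("no depth/quality metadata; quality mask is a no-op")
    return(x)
  }
  g <- as_geno_matrix(x)
  bad <- matrix(FALSE, nrow(g), ncol(g))
  if (!is.null(x$depth)) bad <- bad | (!is.na(x$depth) & x$depth < min_depth)
  if (!is.null(x$gq)) bad <- bad | (!is.na(x$gq) & x$gq < min_gq)
  g[bad] <- NA_integer_
  x$geno <- as_geno_tbl(g)
  x
}

#' @rdname filter_genotypes
#' @export
filter_allele_balance <- function(x, balance_range = c(0.25, 0.75)) {
  x <- as_snp_geno(x)
  if (is.null(x$ad_ref) || is.null(x$ad_alt)) {
    message("no allele-depth metadata; allele-balance filter is a no-op")
    return(x)
  }
  g <- as_geno_matrix(x)
  tot <- x$ad_ref + x$ad_alt
  ratio <- ifelse(tot > 0, x$ad_ref / tot, NA)
  ## applies to heterozygous calls only
  bad <- !is.na(g) & g == 1L & !is.na(ratio) &
    (ratio < balance_range[1] | ratio > balance_range[2])
  g[bad] <- NA_integer_
  x$geno <- as_geno_tbl(g)
  x
}

#' @rdname filter_genotypes
#' @export
filter_loci <- function(x, min_mac = 2, max_missing = 0.5) {
  x <- as_snp_geno(x)
  before <- x
  x <- drop_loci(x, locus_mac(x) >= min_mac)
  r1 <- tibble::tibble(stage = "min_mac", n_loci_in = ncol(before$geno) - 1L,
                       n_loci_out = ncol(x$geno) - 1L, n_calls_masked = 0L)
  before <- x
  x <- drop_loci(x, locus_missingness(x) <= max_missing)
  r2 <- tibble::tibble(stage = "locus_missingness",
                       n_loci_in = ncol(before$geno) - 1L,
                       n_loci_out = ncol(x$geno) - 1L, n_calls_masked = 0L)
  list(genotypes = x, report = dplyr::bind_rows(r1, r2))
}

locus_mac <- function(x) {
  g <- as_geno_matrix(x)
  alt <- colSums(g, na.rm = TRUE)
  n2 <- 2 * colSums(!is.na(g))
  pmin(alt, n2 - alt)
}

locus_missingness <- function(x) {
  colMeans(is.na(as_geno_matrix(x)))
}

drop_loci <- function(x, keep) {
  keep_cols <- c(TRUE, keep)          # sample_id column always kept
  x$geno <- x$geno[, keep_cols, drop = FALSE]
  x$loci <- x$loci[keep, , drop = FALSE]
  for (m in c("depth", "gq", "ad_ref", "ad_alt")) {
    if (!is.null(x[[m]])) x[[m]] <- x[[m]][, keep, drop = FALSE]
  }
  x
}
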