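#' Genotype tables and the `snp_geno` container
#'
#' Throughout the package a *genotype table* is a wide tibble with a
#' `sample_id` character column followed by one integer column per locus.
#' Codes count copies of the alternate allele: `0` (homozygous reference),
#' `1` (heterozygous), `2` (homozygous alternate); `NA` is a missing call.
#'
#' A `snp_geno` object bundles a genotype table with optional per-call
#' metadata (read depth, phred-scaled genotype quality, ref/alt allele
#' depths) and a per-locus annotation table (`locus_id`, `contig`, `pos`,
#' `ref`, `alt`). The metadata are sample-by-locus matrices aligned with the
#' genotype table; they are only required by the quality-mask and
#' allele-balance filters.
#'
#' @param geno genotype table (wide tibble as described above).
#' @param loci optional tibble with columns `locus_id`, `contig`, `pos`,
#'   `ref`, `alt`. Missing columns are filled with defaults (one pseudo-contig
#'   per locus, position 1, alleles A/B).
#' @param depth,gq,ad_ref,ad_alt optional numeric matrices (samples x loci,
#'   dimnames matching `geno`).
#'
#' @return `snp_geno()` returns an object of class `"snp_geno"`; accessors
#'   return the corresponding component.
#' @export
snp_geno <- function(geno, loci = NULL, depth = NULL, gq = NULL,
                     ad_ref = NULL, ad_alt = NULL) {
  geno <- validate_geno_tbl(geno)
  locus_ids <- setdiff(names(geno), "sample_id")
  if (is.null(loci)) {
    loci <- default_loci(locus_ids)
  } else {
    stopifnot(is.data.frame(loci), "locus_id" %in% names(loci))
    loci <- tibble::as_tibble(loci)
    if (!setequal(loci$locus_id, locus_ids)) {
      stop("`loci` table does not match the loci in `geno`")
    }
    loci <- loci[match(locus_ids, loci$locus_id), , drop = FALSE]
    if (is.null(loci$contig)) loci$contig <- loci$locus_id
    if (is.null(loci$pos)) loci$pos <- 1L
    if (is.null(loci$ref)) loci$ref <- "A"
    if (is.null(loci$alt)) loci$alt <- "B"
  }
  for (m in list(depth = depth, gq = gq, ad_ref = ad_ref, ad_alt = ad_alt)) {
    if (!is.null(m)) {
      stopifnot(is.matrix(m),
                nrow(m) == nrow(geno), ncol(m) == length(locus_ids))
    }
  }
  structure(
    list(geno = geno, loci = loci, depth = depth, gq = gq,
         ad_ref = ad_ref, ad_alt = ad_alt),
    class = "snp_geno"
  )
}

default_loci <- function(locus_ids) {
  ## "<name>.<offset>" locus ids carry their within-RAD-locus offset; use it
  ## as the position so spacing rules work on simulated/parsed names too.
  off <- suppressWarnings(as.integer(sub("^.*\\.", "", locus_ids)))
  contig <- ifelse(grepl("\\.", locus_ids), sub("\\.[^.]*$", "", locus_ids),
                   locus_ids)
  tibble::tibble(
    locus_id = locus_ids,
    contig = contig,
    pos = ifelse(is.na(off), 1L, off),
    ref = "A", alt = "B"
  )
}

validate_geno_tbl <- function(geno) {
  stopifnot(is.data.frame(geno))
  geno <- tibble::as_tibble(geno)
  if (names(geno)[1] != "sample_id") {
    stop("genotype table must have `sample_id` as its first column")
  }
  if (anyDuplicated(geno$sample_id)) stop("duplicated sample ids")
  codes <- as.matrix(geno[-1])
  if (!all(codes %in% c(0L, 1L, 2L, NA))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  geno
}

#' @rdname snp_geno
#' @param x a `snp_geno` object or a genotype table.
#' @export
as_snp_geno <- function(x, ...) UseMethod("as_snp_geno")

#' @export
as_snp_geno.snp_geno <- function(x, ...) x

#' @export
as_snp_geno.data.frame <- function(x, ...) snp_geno(x, ...)

#' @rdname snp_geno
#' @export
geno_tbl <- function(x) {
  if (inherits(x, "snp_geno")) x$geno else validate_geno_tbl(x)
}

#' @rdname snp_geno
#' @export
geno_loci <- function(x) as_snp_geno(x)$loci

#' Convert a genotype table to / from an integer matrix
#'
#' @param geno genotype table (or `snp_geno`).
#' @return `as_geno_matrix()`: integer matrix with sample ids as rownames;
#'   `as_geno_tbl()`: the inverse.
#' @export
as_geno_matrix <- function(geno) {
  geno <- geno_tbl(geno)
  m <- as.matrix(geno[-1])
  storage.mode(m) <- "integer"
  rownames(m) <- geno$sample_id
  m
}

#' @rdname as_geno_matrix
#' @param m integer matrix with rownames (samples) and colnames (loci).
#' @export
as_geno_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m))
}

#' @export
print.snp_geno <- function(x, ...) {
  cat(sprintf("<snp_geno> %d samples x %d loci\n",
              nrow(x$geno), ncol(x$geno) - 1L))
  meta <- c("depth", "gq", "ad_ref", "ad_alt")
  have <- meta[!vapply(x[meta], is.null, logical(1))]
  cat("  per-call metadata:",
      if (length(have)) paste(have, collapse = ", ") else "none", "\n")
  miss <- mean(is.na(as_geno_matrix(x)))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Population map constructor
#'
#' A population map links samples to a group label (typically a species) and
#' a role: `"control"` samples define the groups (reference/ascertainment
#' individuals), `"unknown"` samples are to be assigned, `"outgroup"` and
#' `"ntc"` (no-template control) rows are excluded from analysis matrices.
#'
#' @param sample character vector of sample ids (unique).
#' @param group group label per sample.
#' @param role one of `"control"`, `"unknown"`, `"outgroup"`, `"ntc"`.
#' @return tibble with columns `sample`, `group`, `role`.
#' @export
pop_map <- function(sample, group, role = "control") {
  role <- rep_len(role, length(sample))
  stopifnot(!anyDuplicated(sample),
            all(role %in% c("control", "unknown", "outgroup", "ntc")))
  if (any(role == "control" & (is.na(group) | group == ""))) {
    stop("every control sample needs a group label")
  }
  tibble::tibble(sample = as.character(sample),
                 group = as.character(group), role = role)
}

## internal: seed handling -- every stochastic entry point takes `seed`;
## a non-NULL seed makes the call reproducible without touching the
## caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
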