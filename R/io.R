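#' Read a VCF file into a `snp_geno` object
#'
#' Only biallelic SNP records are retained (multi-allelic or indel records
#' are skipped with a message reporting the count). Genotypes are coded as
#' counts of the alternate allele; `./.` becomes a missing call. Per-call
#' `DP`, `GQ` and `AD` fields are parsed when present in the FORMAT column.
#'
#' @param path path to a VCF 4.x file (plain or gzipped).
#' @return a [snp_geno()] object; sample order follows the VCF header.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- vcfR::is.biallelic(vcf) &
    nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "REF"] %in% c("A", "C", "G", "T") &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(sprintf("skipped %d non-biallelic-SNP record(s)", n_skip))
    vcf <- vcf[keep, ]
    fix <- fix[keep, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic SNP records in ", path)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ".",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  codes <- t(matrix(gt_to_code(as.vector(gt)), nrow = nrow(gt)))
  rownames(codes) <- colnames(gt)
  colnames(codes) <- ids
  storage.mode(codes) <- "integer"

  grab_num <- function(el) {
    if (!el %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) return(NULL)
    m <- t(vcfR::extract.gt(vcf, element = el, as.numeric = TRUE))
    dimnames(m) <- dimnames(codes)
    m
  }
  depth <- grab_num("DP")
  gq <- grab_num("GQ")
  ad_ref <- ad_alt <- NULL
  if ("AD" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    ad <- t(vcfR::extract.gt(vcf, element = "AD"))
    ad_ref <- apply(ad, 2, function(x)
      suppressWarnings(as.numeric(sub(",.*", "", x))))
    ad_alt <- apply(ad, 2, function(x)
      suppressWarnings(as.numeric(sub("^[^,]*,", "", x))))
    if (nrow(codes) == 1) {
      ad_ref <- matrix(ad_ref, nrow = 1)
      ad_alt <- matrix(ad_alt, nrow = 1)
    }
    dimnames(ad_ref) <- dimnames(ad_alt) <- dimnames(codes)
  }
  loci <- tibble::tibble(
    locus_id = ids,
    contig = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"]
  )
  snp_geno(as_geno_tbl(codes), loci = loci, depth = depth, gq = gq,
           ad_ref = ad_ref, ad_alt = ad_alt)
}

gt_to_code <- function(gt) {
  gt <- sub(":.*", "", gt)
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  out <- suppressWarnings(as.integer(a1) + as.integer(a2))
  out[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  out
}

#' Write genotypes as a VCF file
#'
#' Plain-text VCF 4.2 output with one record per locus (GT, plus DP/GQ/AD
#' when the object carries them). `read_vcf(write_vcf(x))` round-trips the
#' codes, ids, sample order and missingness.
#'
#' @param x a `snp_geno` object or genotype table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  x <- as_snp_geno(x)
  g <- as_geno_matrix(x)
  loci <- x$loci
  ref <- ifelse(loci$ref %in% c("A", "C", "G", "T"), loci$ref, "A")
  alt <- ifelse(loci$alt %in% c("A", "C", "G", "T"), loci$alt, "G")
  gt_str <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow = nrow(g))
  gt_str[is.na(g)] <- "./."
  fmt <- "GT"
  if (!is.null(x$depth)) {
    fmt <- paste0(fmt, ":DP")
    dp <- ifelse(is.na(x$depth), ".", format(x$depth, trim = TRUE))
    gt_str <- matrix(paste0(gt_str, ":", dp), nrow = nrow(g))
  }
  if (!is.null(x$gq)) {
    fmt <- paste0(fmt, ":GQ")
    gq <- ifelse(is.na(x$gq), ".", format(x$gq, trim = TRUE))
    gt_str <- matrix(paste0(gt_str, ":", gq), nrow = nrow(g))
  }
  if (!is.null(x$ad_ref) && !is.null(x$ad_alt)) {
    fmt <- paste0(fmt, ":AD")
    ad <- matrix(paste0(ifelse(is.na(x$ad_ref), ".", x$ad_ref), ",",
                        ifelse(is.na(x$ad_alt), ".", x$ad_alt)),
                 nrow = nrow(g))
    gt_str <- matrix(paste0(gt_str, ":", ad), nrow = nrow(g))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snppanel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(x$depth))
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if (!is.null(x$gq))
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    if (!is.null(x$ad_ref))
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(g)), function(j) {
    paste(c(loci$contig[j], loci$pos[j], loci$locus_id[j], ref[j], alt[j],
            ".", "PASS", ".", fmt, gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a long-format genotype table (microfluidic assay export dialect)
#'
#' Expects a CSV with columns `sample_id`, `assay`, `call` and optionally
#' `replicate`. Calls are allele pairs such as `"A:A"` or `"A:G"`;
#' `"No Call"`, `"Invalid"` or blank are missing. Allele letters are mapped
#' to codes through a per-locus allele dictionary; when `alleles` is not
#' supplied the dictionary is inferred from the observed letters (first
#' allele in alphabetical order is taken as reference, with a message).
#' Repeated `(sample, assay)` rows (or an explicit `replicate` column) stack
#' into a replicate table.
#'
#' @param path CSV path.
#' @param alleles optional tibble `locus_id`, `ref`, `alt` naming the two
#'   valid allele letters per assay. A call letter outside the dictionary is
#'   a fatal error naming the locus.
#' @return a genotype table, or a replicate table (columns `sample_id`,
#'   `replicate`, then loci) when replicates are present.
#' @export
read_genotype_table <- function(path, alleles = NULL) {
  raw <- tibble::as_tibble(read.csv(path, check.names = FALSE,
                                    colClasses = "character"))
  need <- c("sample_id", "assay", "call")
  if (!all(need %in% names(raw))) {
    stop("genotype table needs columns: ", paste(need, collapse = ", "))
  }
  assays <- unique(raw$assay)
  missing_call <- c("No Call", "NoCall", "Invalid", "", NA)
  parsed <- strsplit(ifelse(raw$call %in% missing_call, NA, raw$call), ":",
                     fixed = TRUE)
  bad <- !is.na(raw$call) & !(raw$call %in% missing_call) &
    lengths(parsed) != 2
  if (any(bad)) stop("malformed call(s): ", raw$call[which(bad)[1]])

  if (is.null(alleles)) {
    alleles <- dplyr::bind_rows(lapply(assays, function(a) {
      letters_seen <- sort(unique(unlist(parsed[raw$assay == a])))
      if (length(letters_seen) > 2) {
        stop("more than two alleles observed at locus ", a)
      }
      if (length(letters_seen) == 0) letters_seen <- c("A", "B")
      if (length(letters_seen) == 1) letters_seen <- c(letters_seen, NA)
      tibble::tibble(locus_id = a, ref = letters_seen[1],
                     alt = letters_seen[2])
    }))
    message("allele dictionary inferred from data (alphabetical ref)")
  }
  dict <- alleles[match(raw$assay, alleles$locus_id), ]
  if (anyNA(dict$locus_id)) {
    stop("no allele dictionary entry for locus ",
         raw$assay[which(is.na(dict$locus_id))[1]])
  }
  code1 <- allele_code(vapply(parsed, `[`, character(1), 1), dict,
                       raw$assay)
  code2 <- allele_code(vapply(parsed, `[`, character(1), 2), dict,
                       raw$assay)
  raw$code <- code1 + code2

  if (!"replicate" %in% names(raw)) {
    raw <- raw %>%
      dplyr::group_by(.data$sample_id, .data$assay) %>%
      dplyr::mutate(replicate = dplyr::row_number()) %>%
      dplyr::ungroup()
  } else {
    raw$replicate <- as.integer(raw$replicate)
  }
  wide <- raw[c("sample_id", "replicate", "assay", "code")] %>%
    tidyr::pivot_wider(names_from = "assay", values_from = "code") %>%
    dplyr::arrange(.data$sample_id, .data$replicate)
  wide <- wide[c("sample_id", "replicate", assays)]
  if (all(tapply(wide$replicate, wide$sample_id, length) == 1)) {
    wide$replicate <- NULL
    wide
  } else {
    wide
  }
}

allele_code <- function(letter, dict, assay) {
  out <- rep(NA_integer_, length(letter))
  out[!is.na(letter) & letter == dict$ref] <- 0L
  out[!is.na(letter) & letter == dict$alt] <- 1L
  bad <- !is.na(letter) & is.na(out)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("allele '%s' not in the dictionary of locus %s",
                 letter[i], assay[i]))
  }
  out
}

#' Write genotypes as a long-format genotype table
#'
#' Inverse of [read_genotype_table()]: emits `sample_id[, replicate], assay,
#' call` rows with allele-pair calls and `"No Call"` for missing.
#'
#' @param x genotype table or replicate table.
#' @param path output CSV path.
#' @param alleles optional `locus_id`, `ref`, `alt` dictionary; defaults to
#'   `A`/`B` letters for every locus.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(x, path, alleles = NULL) {
  x <- tibble::as_tibble(x)
  has_rep <- "replicate" %in% names(x)
  loci <- setdiff(names(x), c("sample_id", "replicate"))
  if (is.null(alleles)) {
    alleles <- tibble::tibble(locus_id = loci, ref = "A", alt = "B")
  }
  long <- tidyr::pivot_longer(x, dplyr::all_of(loci), names_to = "assay",
                              values_to = "code")
  dict <- alleles[match(long$assay, alleles$locus_id), ]
  long$call <- dplyr::case_when(
    is.na(long$code) ~ "No Call",
    long$code == 0 ~ paste0(dict$ref, ":", dict$ref),
    long$code == 1 ~ paste0(dict$ref, ":", dict$alt),
    long$code == 2 ~ paste0(dict$alt, ":", dict$alt)
  )
  cols <- c("sample_id", if (has_rep) "replicate", "assay", "call")
  write.csv(long[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a population map (TSV: sample, group, role)
#'
#' @param path TSV path.
#' @return [pop_map()] tibble.
#' @export
read_pop_map <- function(path) {
  df <- read.delim(path, colClasses = "character")
  if (!all(c("sample", "group") %in% names(df))) {
    stop("population map needs columns sample, group[, role]")
  }
  if (is.null(df$role)) df$role <- "control"
  pop_map(df$sample, df$group, df$role)
}

#' @rdname read_pop_map
#' @param popmap a [pop_map()] tibble.
#' @export
write_pop_map <- function(popmap, path) {
  write.table(popmap, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree an `ape` `"phylo"` object (e.g. from [upgma_tree()]).
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "upgma_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
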