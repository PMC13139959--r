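#' Select a SNP subset inside an F_ST window
#'
#' Eligible loci have per-locus theta inside the closed window. When more
#' than `subset_size` are eligible the selection rule picks among them:
#' `"random"` draws a seeded uniform sample (the default; which loci inside
#' a window end up on an assay is otherwise arbitrary), `"central"` takes
#' the loci closest to the window midpoint. Fewer eligible loci than
#' `subset_size` are all returned with a warning.
#'
#' @param stats per-locus stats with `locus_id` and `theta` columns (from
#'   [locus_summary()] with a popmap, or [wc_theta()]).
#' @param window closed theta interval, e.g. `c(0.3, 0.5)`.
#' @param subset_size target number of loci (default 200).
#' @param rule `"random"` or `"central"`.
#' @param seed optional integer seed for the random rule.
#' @return tibble `locus_id`, `theta`, with the window stored in the
#'   `"window"` attribute.
#' @export
subset_by_fst_window <- function(stats, window = c(0.3, 0.5),
                                 subset_size = 200,
                                 rule = c("random", "central"),
                                 seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(length(window) == 2, subset_size >= 1)
  if (!(window[1] >= 0 && window[1] < window[2] && window[2] <= 1)) {
    stop("window must satisfy 0 <= low < high <= 1")
  }
  eligible <- stats[!is.na(stats$theta) &
                      stats$theta >= window[1] & stats$theta <= window[2], ]
  eligible <- eligible[c("locus_id", "theta")]
  if (nrow(eligible) == 0) {
    warning("no loci with theta inside the window")
  } else if (nrow(eligible) < subset_size) {
    warning(sprintf("only %d of the requested %d loci inside the window",
                    nrow(eligible), subset_size))
  } else if (nrow(eligible) > subset_size) {
    eligible <- switch(rule,
      random = with_seed(seed,
        eligible[sort(sample.int(nrow(eligible), subset_size)), ]),
      central = {
        mid <- mean(window)
        eligible[order(abs(eligible$theta - mid))[seq_len(subset_size)], ]
      })
  }
  attr(eligible, "window") <- window
  eligible
}

#' Score a SNP subset by PCA variance and cluster separation
#'
#' Runs a PCA on the genotype codes restricted to the subset loci
#' (per-locus mean imputation of missing calls, column centering, no
#' variance scaling so divergence-driven loci dominate) and reports the
#' cumulative variance of PC1+PC2 together with the mean silhouette width
#' of the known groups in the PC1-PC2 plane. A subset "separates the
#' clusters" when the silhouette exceeds `distinct_threshold`.
#'
#' @param x genotype table or `snp_geno`.
#' @param loci character vector of locus ids, or a subset tibble from
#'   [subset_by_fst_window()].
#' @param popmap [pop_map()] supplying the known group labels.
#' @param distinct_threshold silhouette needed to call the clusters
#'   distinct (default 0.5).
#' @return one-row tibble `n_loci`, `var_pc12` (percent), `silhouette`,
#'   `distinct`; the PCA result is attached as attribute `"pca"`.
#' @export
score_subset <- function(x, loci, popmap, distinct_threshold = 0.5) {
  if (is.data.frame(loci)) loci <- loci$locus_id
  g <- as_geno_matrix(x)
  if (nrow(g) < 3) stop("scoring needs at least three samples")
  missing_loci <- setdiff(loci, colnames(g))
  if (length(missing_loci)) {
    stop("subset loci absent from the genotype table: ",
         paste(head(missing_loci, 3), collapse = ", "))
  }
  ord <- pca_genotypes(g[, loci, drop = FALSE])
  sc <- as.matrix(ord$points[, c("axis1", "axis2")])
  labels <- popmap$group[match(rownames(g), popmap$sample)]
  keep <- !is.na(labels)
  sil <- cluster_silhouette(sc[keep, , drop = FALSE], labels[keep])
  var12 <- sum(ord$variance$pct[1:2])
  out <- tibble::tibble(n_loci = length(loci), var_pc12 = var12,
                        silhouette = sil,
                        distinct = !is.na(sil) & sil > distinct_threshold)
  attr(out, "pca") <- ord
  out
}

cluster_silhouette <- function(coords, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Score and rank several subsets
#'
#' @param subsets named list of locus-id vectors (or subset tibbles).
#' @inheritParams score_subset
#' @return tibble, one row per subset, ranked by the distinct-cluster
#'   criterion and then by PC1+PC2 variance.
#' @export
score_subsets <- function(x, subsets, popmap, distinct_threshold = 0.5) {
  if (is.null(names(subsets))) names(subsets) <- paste0("subset", seq_along(subsets))
  out <- dplyr::bind_rows(lapply(subsets, function(s) {
    score_subset(x, s, popmap, distinct_threshold)
  }), .id = "subset")
  out[order(-out$distinct, -out$var_pc12), ]
}

#' Find species-diagnostic SNPs among control samples
#'
#' A locus is diagnostic for group S when every control of S is homozygous
#' for one allele and every control of every other group is homozygous for
#' the other allele, with no missing calls among controls.
#'
#' @inheritParams score_subset
#' @return tibble `locus_id`, `species` (the diagnosed group), restricted
#'   to diagnostic loci.
#' @export
find_diagnostic_snps <- function(x, popmap) {
  g <- as_geno_matrix(x)
  ctrl <- popmap[popmap$role == "control", ]
  stopifnot(nrow(ctrl) > 0)
  g <- g[rownames(g) %in% ctrl$sample, , drop = FALSE]
  grp <- ctrl$group[match(rownames(g), ctrl$sample)]
  hits <- lapply(unique(grp), function(s) {
    gs <- g[grp == s, , drop = FALSE]
    go <- g[grp != s, , drop = FALSE]
    ok <- !colAnyNA(gs) & !colAnyNA(go) &
      ((colAll(gs == 0L) & colAll(go == 2L)) |
         (colAll(gs == 2L) & colAll(go == 0L)))
    tibble::tibble(locus_id = colnames(g)[ok], species = s)
  })
  dplyr::bind_rows(hits)
}

colAnyNA <- function(m) colSums(is.na(m)) > 0
colAll <- function(m) colSums(m, na.rm = TRUE) == nrow(m)

#' Exclude candidate SNPs too close to another SNP
#'
#' Assay design needs clean primer-binding sequence around the target SNP:
#' a candidate is removed when any other SNP (candidate or not) lies within
#' `min_gap` base pairs of it on the same contig/RAD locus.
#'
#' @param candidates character vector of candidate locus ids.
#' @param loci locus annotation tibble (`locus_id`, `contig`, `pos`), e.g.
#'   [geno_loci()] output. Candidates without position information are kept
#'   with a warning.
#' @param min_gap minimum distance in bp (default 30); pairs at distance
#'   `<= min_gap` are excluded.
#' @return the surviving candidate ids.
#' @export
apply_spacing_constraint <- function(candidates, loci, min_gap = 30) {
  info <- loci[match(candidates, loci$locus_id), ]
  no_pos <- is.na(info$pos) | is.na(info$contig)
  if (any(no_pos)) {
    warning("no position for ", sum(no_pos),
            " candidate(s); kept unchecked")
  }
  keep <- vapply(seq_along(candidates), function(i) {
    if (no_pos[i]) return(TRUE)
    same <- loci$contig == info$contig[i] & loci$locus_id != candidates[i]
    !any(abs(loci$pos[same] - info$pos[i]) <= min_gap, na.rm = TRUE)
  }, logical(1))
  candidates[keep]
}

#' Assemble the final diagnostic panel
#'
#' Takes the best-scoring window subset, ranks its loci (diagnostic loci
#' first, then by decreasing theta), keeps the top `target_size`, adds any
#' user-supplied extra loci (e.g. informative barcode SNPs), de-duplicates,
#' and re-scores the assembled panel.
#'
#' @inheritParams score_subset
#' @param subset subset tibble (needs `locus_id`, `theta`) or locus ids.
#' @param diagnostic optional tibble from [find_diagnostic_snps()].
#' @param extra_loci extra locus ids appended after selection.
#' @param target_size panel size drawn from the subset (default 19).
#' @return list with `panel` (tibble `locus_id`, `theta`, `diagnostic_for`,
#'   `source`) and `score` (one-row tibble from [score_subset()]).
#' @export
assemble_panel <- function(x, subset, popmap, diagnostic = NULL,
                           extra_loci = character(), target_size = 19,
                           distinct_threshold = 0.5) {
  if (!is.data.frame(subset)) {
    subset <- tibble::tibble(locus_id = subset, theta = NA_real_)
  }
  if (target_size > nrow(subset)) {
    stop("target_size exceeds the number of available subset loci")
  }
  diag_ids <- if (is.null(diagnostic)) character() else diagnostic$locus_id
  ord <- order(!(subset$locus_id %in% diag_ids), -subset$theta)
  chosen <- subset[ord[seq_len(target_size)], ]
  extra_new <- setdiff(extra_loci, chosen$locus_id)
  panel <- dplyr::bind_rows(
    tibble::tibble(locus_id = chosen$locus_id, theta = chosen$theta,
                   source = "subset"),
    tibble::tibble(locus_id = extra_new, theta = NA_real_,
                   source = "extra")
  )
  panel$diagnostic_for <- if (is.null(diagnostic)) NA_character_ else
    diagnostic$species[match(panel$locus_id, diagnostic$locus_id)]
  score <- score_subset(x, panel$locus_id, popmap, distinct_threshold)
  if (!isTRUE(score$distinct)) {
    warning("assembled panel does not separate the groups distinctly")
  }
  list(panel = panel, score = score)
}
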