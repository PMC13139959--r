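#' Run the discovery phase: filter, characterise, and select a panel
#'
#' Orchestrates the panel-design phase end to end: genotype filtering,
#' per-locus diversity and differentiation statistics, F_ST-window subset
#' selection with PCA/silhouette scoring, diagnostic-SNP detection, the
#' assay spacing constraint, and final panel assembly. With `x = NULL` a
#' study is simulated first (see [sim_study()]), so the whole phase runs
#' from a single seed.
#'
#' @param x input genotypes (`snp_geno` or genotype table), e.g. from
#'   [read_vcf()]; `NULL` to simulate.
#' @param popmap [pop_map()] for the discovery samples (required when `x`
#'   is given).
#' @param sim named list of arguments for [sim_study()] when simulating.
#' @param filter named list of arguments for [filter_genotypes()].
#' @param windows list of theta windows to evaluate (defaults to the three
#'   standard bands 0.3-0.5, 0.5-0.7, 0.8-1).
#' @param subset_size loci per window subset (default 200).
#' @param target_size panel loci drawn from the best subset (default 19).
#' @param extra_loci extra locus ids forced into the panel.
#' @param min_gap assay spacing constraint in bp (default 30).
#' @param seed master seed; all stages derive substreams from it.
#' @return list with `genotypes`, `popmap`, `filter_report`, `stats`,
#'   `subsets`, `scores`, `diagnostic`, `panel`, `panel_score`, `seed`.
#' @export
run_discovery <- function(x = NULL, popmap = NULL, sim = list(),
                          filter = list(),
                          windows = list(c(0.3, 0.5), c(0.5, 0.7),
                                         c(0.8, 1)),
                          subset_size = 200, target_size = 19,
                          extra_loci = character(), min_gap = 30,
                          seed = NULL) {
  seeds <- derive_seeds(seed, 3)
  if (is.null(x)) {
    study <- do.call(sim_study, c(sim, list(seed = seeds[[1]])))
    x <- study$genotypes
    popmap <- study$popmap
  }
  if (is.null(popmap)) stop("popmap is required with user-supplied genotypes")
  x <- as_snp_geno(x)
  filtered <- do.call(filter_genotypes, c(list(x), filter))
  x <- filtered$genotypes
  stats <- locus_summary(x, popmap)
  names(windows) <- vapply(windows, function(w)
    sprintf("fst_%.2g_%.2g", w[1], w[2]), character(1))
  subsets <- lapply(windows, function(w) {
    suppressWarnings(subset_by_fst_window(stats, w, subset_size,
                                          seed = seeds[[2]]))
  })
  subsets <- subsets[vapply(subsets, nrow, integer(1)) > 0]
  if (length(subsets) == 0) stop("no window produced a non-empty subset")
  scores <- score_subsets(x, lapply(subsets, `[[`, "locus_id"), popmap)
  best <- subsets[[scores$subset[1]]]
  diagnostic <- find_diagnostic_snps(x, popmap)
  spaced <- apply_spacing_constraint(best$locus_id, geno_loci(x), min_gap)
  best <- best[best$locus_id %in% spaced, ]
  assembled <- assemble_panel(x, best, popmap, diagnostic, extra_loci,
                              min(target_size, nrow(best)))
  list(genotypes = x, popmap = popmap, filter_report = filtered$report,
       stats = stats, subsets = subsets, scores = scores,
       diagnostic = diagnostic, panel = assembled$panel,
       panel_score = assembled$score, seed = seed)
}

#' Run the identification phase: consensus genotyping and assignment
#'
#' Takes replicated panel genotyping runs for controls and unknowns,
#' performs replicate and locus quality control, builds consensus
#' genotypes, excludes outgroup-like samples (consensus genotyping rate
#' below `outgroup_rate`, the signature of off-target genera), assigns the
#' remaining unknowns to species by allele sharing with the controls, and
#' corroborates the assignments with a UPGMA dendrogram, a PCoA and (when
#' `k_range` is given) cross-validated admixture analysis.
#'
#' @param replicates replicate table (`sample_id`, `replicate`, loci).
#' @param popmap [pop_map()] with control and unknown roles.
#' @param panel locus ids to use (default: all loci in `replicates`).
#' @param min_call_rate replicate exclusion threshold in percent
#'   (default 85).
#' @param locus_min_success locus success threshold (default 0.8).
#' @param threshold assignment sharing threshold (default 0.80).
#' @param outgroup_rate consensus genotyping rate below which a sample is
#'   excluded as outgroup-like (default 0.4).
#' @param n_boot UPGMA bootstrap replicates (default 0).
#' @param k_range candidate K values for admixture CV, or `NULL` to skip.
#' @param seed master seed.
#' @return list with `consensus`, `qc`, `locus_success`, `excluded`,
#'   `assignments`, `tree`, `ordination`, `k_selection`, `admixture`,
#'   `seed`.
#' @export
run_identification <- function(replicates, popmap, panel = NULL,
                               min_call_rate = 85, locus_min_success = 0.8,
                               threshold = 0.80, outgroup_rate = 0.4,
                               n_boot = 0, k_range = NULL, seed = NULL) {
  if (!any(popmap$role == "control")) stop("no control samples in popmap")
  seeds <- derive_seeds(seed, 3)
  loci_all <- setdiff(names(replicates), c("sample_id", "replicate"))
  panel <- panel %||% loci_all
  panel <- intersect(panel, loci_all)
  if (length(panel) == 0) {
    stop("none of the panel loci are present in the replicate table")
  }
  replicates <- replicates[c("sample_id", "replicate", panel)]
  success <- locus_success_filter(replicates, locus_min_success)
  replicates <- replicates[c("sample_id", "replicate",
                             success$locus_id[success$retained])]
  cons <- build_consensus(replicates, min_call_rate)
  g <- as_geno_matrix(cons$genotypes)
  rate <- rowMeans(!is.na(g))
  excluded <- tibble::tibble(sample_id = rownames(g)[rate < outgroup_rate],
                             genotyping_rate = rate[rate < outgroup_rate])
  keep <- rownames(g)[rate >= outgroup_rate]
  geno <- cons$genotypes[cons$genotypes$sample_id %in% keep, ]
  assignments <- assign_by_sharing(geno, popmap, threshold)
  d <- allele_sharing_distance(geno)
  tree <- upgma_tree(d, geno = geno, n_boot = n_boot, seed = seeds[[1]])
  ordination <- pcoa(d)
  ksel <- adm <- NULL
  if (!is.null(k_range)) {
    ksel <- select_k(geno, k_range, seed = seeds[[2]])
    adm <- admixture_em(geno, ksel$best_k, seed = seeds[[3]])
  }
  list(consensus = cons$genotypes, qc = cons$qc,
       agreement = cons$agreement, locus_success = success,
       excluded = excluded, assignments = assignments, tree = tree,
       ordination = ordination, k_selection = ksel, admixture = adm,
       seed = seed)
}
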