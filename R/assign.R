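#' Bowcock allele-sharing distance between samples
#'
#' At each locus the similarity of two diploid genotypes is the proportion
#' of allele copies they share: 1 for identical genotypes, 0.5 for a
#' heterozygote vs either homozygote, 0 for opposite homozygotes. The
#' distance of a pair is one minus the mean similarity over loci called in
#' both; it equals `1 - match_score/100` for the same pair.
#'
#' @param x genotype table or `snp_geno` (at least two samples).
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#'   Pairs with no shared loci are `NA` with a warning.
#' @export
allele_sharing_distance <- function(x) {
  g <- as_geno_matrix(x)
  if (nrow(g) < 2) stop("need at least two samples")
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(g[i, ]) & !is.na(g[j, ])
      if (!any(ok)) {
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      d[i, j] <- d[j, i] <- mean(abs(g[i, ok] - g[j, ok])) / 2
    }
  }
  if (anyNA(d)) warning("sample pair(s) with no shared loci")
  d
}

#' Assign unknown samples to species by allele sharing with controls
#'
#' The genotypic information a sample shares with a control group is 100
#' times the mean allele-sharing similarity (1 minus distance) with that
#' group's control samples. A sample is assigned to the group with the
#' highest shared fraction provided it reaches `threshold`; otherwise it is
#' reported unassigned with its two top fractions — the signature of an
#' admixed or intermediate individual.
#'
#' @param x genotype table or `snp_geno` holding controls and unknowns.
#' @param popmap [pop_map()]; `role == "control"` rows define the groups.
#'   Samples with other roles (or absent from the map) are treated as
#'   unknowns; `ntc` and `outgroup` rows are skipped.
#' @param threshold minimum shared fraction for assignment (default 0.80).
#' @return tibble with one row per unknown: `sample_id`, one `share_<group>`
#'   column per control group (percent), `assigned` (group label or
#'   `"unassigned"`), `second_group`, `second_share`.
#' @export
assign_by_sharing <- function(x, popmap, threshold = 0.80) {
  g <- as_geno_matrix(x)
  ctrl <- popmap[popmap$role == "control" & popmap$sample %in% rownames(g), ]
  if (nrow(ctrl) == 0) stop("no control samples in the genotype table")
  skip <- popmap$sample[popmap$role %in% c("ntc", "outgroup")]
  unknowns <- setdiff(rownames(g), c(ctrl$sample, skip))
  groups <- unique(ctrl$group)
  d <- allele_sharing_distance(x)
  share <- sapply(groups, function(grp) {
    members <- ctrl$sample[ctrl$group == grp]
    100 * rowMeans(1 - d[unknowns, members, drop = FALSE], na.rm = TRUE)
  })
  share <- matrix(share, nrow = length(unknowns),
                  dimnames = list(unknowns, groups))
  out <- tibble::as_tibble(share, rownames = "sample_id")
  names(out)[-1] <- paste0("share_", groups)
  ord <- t(apply(share, 1, order, decreasing = TRUE))
  best <- groups[ord[, 1]]
  best_share <- share[cbind(seq_len(nrow(share)), ord[, 1])]
  out$assigned <- ifelse(best_share >= 100 * threshold, best, "unassigned")
  if (length(groups) > 1) {
    out$second_group <- groups[ord[, 2]]
    out$second_share <- share[cbind(seq_len(nrow(share)), ord[, 2])]
  } else {
    out$second_group <- NA_character_
    out$second_share <- NA_real_
  }
  out
}

#' Multilocus genotype (MLG) matching
#'
#' Groups samples with identical genotype vectors; repeated MLGs indicate
#' duplicated individuals or clones. In the default exact mode two samples
#' match only when their vectors agree everywhere, missing pattern
#' included; with `missing_wildcard = TRUE` a missing call matches any
#' genotype.
#'
#' @param x genotype table or `snp_geno`.
#' @param missing_wildcard treat missing calls as wildcards (default off).
#' @return list with `samples` (tibble `sample_id`, `mlg`, `n_in_mlg`) and
#'   `summary` (one-row tibble: `n_samples`, `n_unique_mlg`,
#'   `n_repeated_mlg`).
#' @export
multilocus_matches <- function(x, missing_wildcard = FALSE) {
  g <- as_geno_matrix(x)
  n <- nrow(g)
  if (!missing_wildcard) {
    key <- apply(g, 1, paste, collapse = ",")
    mlg <- as.integer(factor(key, levels = unique(key)))
  } else {
    ## wildcard matching is not transitive; group greedily by first match
    mlg <- integer(n)
    next_id <- 0L
    for (i in seq_len(n)) {
      hit <- 0L
      for (j in seq_len(i - 1L)) {
        ok <- !is.na(g[i, ]) & !is.na(g[j, ])
        if (all(g[i, ok] == g[j, ok])) { hit <- mlg[j]; break }
      }
      if (hit == 0L) { next_id <- next_id + 1L; hit <- next_id }
      mlg[i] <- hit
    }
  }
  counts <- table(mlg)
  samples <- tibble::tibble(sample_id = rownames(g), mlg = mlg,
                            n_in_mlg = as.integer(counts[as.character(mlg)]))
  list(samples = samples,
       summary = tibble::tibble(
         n_samples = n,
         n_unique_mlg = length(counts),
         n_repeated_mlg = sum(counts > 1)))
}

#' Frequency-based population assignment test
#'
#' Log-likelihood of each sample's multilocus genotype under Hardy-Weinberg
#' proportions with each control group's allele frequencies. For control
#' samples the frequencies of their own group are re-estimated leaving the
#' sample out, so a control never scores against its own alleles. Zero (or
#' unit) frequencies are floored at `1/(2 N_G + 1)` before taking logs.
#'
#' @inheritParams assign_by_sharing
#' @return tibble per sample: `sample_id`, `loglik_<group>` columns,
#'   `assigned` (argmax group), `tie` flag for equal likelihoods.
#' @export
frequency_assignment_test <- function(x, popmap) {
  g <- as_geno_matrix(x)
  ctrl <- popmap[popmap$role == "control" & popmap$sample %in% rownames(g), ]
  if (nrow(ctrl) == 0) stop("no control samples")
  skip <- popmap$sample[popmap$role %in% c("ntc", "outgroup")]
  samples <- setdiff(rownames(g), skip)
  groups <- unique(ctrl$group)
  ## per-group alt-allele counts and call counts
  cnt <- lapply(groups, function(grp) {
    gk <- g[rownames(g) %in% ctrl$sample[ctrl$group == grp], , drop = FALSE]
    list(alt = colSums(gk, na.rm = TRUE), n = colSums(!is.na(gk)))
  })
  names(cnt) <- groups
  ll <- matrix(NA_real_, length(samples), length(groups),
               dimnames = list(samples, groups))
  own <- ctrl$group[match(samples, ctrl$sample)]
  for (i in seq_along(samples)) {
    gi <- g[samples[i], ]
    for (k in seq_along(groups)) {
      alt <- cnt[[k]]$alt
      n <- cnt[[k]]$n
      if (!is.na(own[i]) && own[i] == groups[k]) {   # leave-one-out
        alt <- alt - ifelse(is.na(gi), 0, gi)
        n <- n - !is.na(gi)
      }
      p <- ifelse(n > 0, alt / (2 * n), NA)
      floor_p <- 1 / (2 * n + 1)
      p <- pmin(pmax(p, floor_p), 1 - floor_p)
      ok <- !is.na(gi) & !is.na(p)
      ll[i, k] <- sum(gi[ok] * log(p[ok]) +
                        (2 - gi[ok]) * log(1 - p[ok]) +
                        log(ifelse(gi[ok] == 1L, 2, 1)))
    }
  }
  out <- tibble::as_tibble(ll, rownames = "sample_id")
  names(out)[-1] <- paste0("loglik_", groups)
  best <- apply(ll, 1, which.max)
  out$assigned <- groups[best]
  out$tie <- apply(ll, 1, function(v) sum(abs(v - max(v)) < 1e-9) > 1)
  out
}
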