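#' Per-locus diversity summary
#'
#' For every locus, computes the number of genotyped samples `n`, minor
#' allele frequency `maf`, observed heterozygosity `h_o`, unbiased gene
#' diversity `h_s` and polymorphic information content `pic`. With minor
#' allele frequency `p` over the `2n` non-missing allele copies and
#' `q = 1 - p`:
#' \deqn{H_S = \frac{2n}{2n-1}\,(1 - p^2 - q^2), \qquad
#'       PIC = 1 - p^2 - q^2 - 2 p^2 q^2.}
#' `H_S` carries Nei's small-sample correction; `PIC` is the Botstein
#' biallelic form, maximal at 0.375 when `p = 0.5`. Statistics use
#' pairwise-complete calls, so `n` varies across loci. A locus with no
#' calls gets `NA` statistics; a monomorphic locus has `h_s = pic = 0`.
#'
#' @param x genotype table or `snp_geno`.
#' @param popmap optional [pop_map()]; when supplied, a per-locus
#'   Weir-Cockerham `theta` column is added (computed across the map's
#'   groups) and, with `by_group = TRUE`, per-group summary blocks are
#'   appended.
#' @param by_group also compute the summary within each group.
#' @return tibble with one row per locus (and per group block when
#'   requested; the pooled block has `group = "all"`).
#' @export
locus_summary <- function(x, popmap = NULL, by_group = FALSE) {
  g <- as_geno_matrix(x)
  out <- locus_summary_matrix(g)
  out <- tibble::add_column(out, group = "all", .before = 1)
  if (!is.null(popmap)) {
    th <- wc_theta(x, popmap)
    out$theta <- th$theta[match(out$locus_id, th$locus_id)]
    if (by_group) {
      blocks <- lapply(unique(popmap$group[!is.na(popmap$group)]),
                       function(grp) {
        ids <- popmap$sample[popmap$group == grp & !is.na(popmap$group)]
        b <- locus_summary_matrix(g[rownames(g) %in% ids, , drop = FALSE])
        tibble::add_column(b, group = grp, .before = 1)
      })
      out <- dplyr::bind_rows(out, dplyr::bind_rows(blocks))
    }
  }
  out
}

locus_summary_matrix <- function(g) {
  n <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  p_alt <- ifelse(n > 0, alt / (2 * n), NA)
  maf <- pmin(p_alt, 1 - p_alt)
  h_o <- ifelse(n > 0, colSums(g == 1L, na.rm = TRUE) / n, NA)
  p <- maf
  q <- 1 - p
  het_exp <- 1 - p^2 - q^2
  h_s <- ifelse(n > 0, (2 * n / pmax(2 * n - 1, 1)) * het_exp, NA)
  pic <- het_exp - 2 * p^2 * q^2
  tibble::tibble(locus_id = colnames(g), n = unname(n), maf = unname(maf),
                 h_o = unname(h_o), h_s = unname(h_s), pic = unname(pic))
}

#' Per-locus Weir-Cockerham theta (F_ST)
#'
#' Computes the Weir & Cockerham (1984) variance components per locus from
#' sample sizes, allele frequencies and observed heterozygote frequencies in
#' each group: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals), with
#' `theta = a / (a + b + c)`. The estimator can be negative near zero
#' differentiation; loci where the denominator is zero (or fewer than two
#' groups are genotyped) are `NA`.
#'
#' @param x genotype table or `snp_geno`.
#' @param popmap [pop_map()]; all samples present in both `x` and the map
#'   with a non-missing group are used.
#' @return tibble `locus_id`, `a`, `b`, `c`, `theta`.
#' @export
wc_theta <- function(x, popmap) {
  g <- as_geno_matrix(x)
  popmap <- popmap[!is.na(popmap$group) & popmap$sample %in% rownames(g), ]
  groups <- unique(popmap$group)
  if (length(groups) < 2) stop("wc_theta needs at least two groups")
  L <- ncol(g)
  nmat <- pmat <- hmat <- matrix(0, nrow = L, ncol = length(groups))
  for (k in seq_along(groups)) {
    gk <- g[rownames(g) %in% popmap$sample[popmap$group == groups[k]], ,
            drop = FALSE]
    nk <- colSums(!is.na(gk))
    nmat[, k] <- nk
    pmat[, k] <- ifelse(nk > 0, colSums(gk, na.rm = TRUE) / (2 * nk), 0)
    hmat[, k] <- ifelse(nk > 0, colSums(gk == 1L, na.rm = TRUE) / nk, 0)
  }
  r <- rowSums(nmat > 0)
  ntot <- rowSums(nmat)
  nbar <- ifelse(r > 0, ntot / r, NA)
  nc <- ifelse(r > 1, (ntot - rowSums(nmat^2) / ntot) / (r - 1), NA)
  pbar <- ifelse(ntot > 0, rowSums(nmat * pmat) / ntot, NA)
  s2 <- ifelse(r > 1, rowSums(nmat * (pmat - pbar)^2) / ((r - 1) * nbar), NA)
  hbar <- ifelse(ntot > 0, rowSums(nmat * hmat) / ntot, NA)

  ok <- r >= 2 & nbar > 1 & nc > 0
  a <- b <- cc <- rep(NA_real_, L)
  inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2
  a[ok] <- (nbar[ok] / nc[ok]) *
    (s2[ok] - (inner[ok] - hbar[ok] / 4) / (nbar[ok] - 1))
  b[ok] <- (nbar[ok] / (nbar[ok] - 1)) *
    (inner[ok] - ((2 * nbar[ok] - 1) / (4 * nbar[ok])) * hbar[ok])
  cc[ok] <- hbar[ok] / 2
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & abs(denom) > 0, a / denom, NA)
  tibble::tibble(locus_id = colnames(g), a = a, b = b, c = cc,
                 theta = theta)
}

#' Multilocus pairwise Weir-Cockerham F_ST with bootstrap CIs
#'
#' For every pair of groups, the multilocus estimate is the ratio of summed
#' variance components over loci, `sum(a) / sum(a + b + c)`. Percentile
#' confidence intervals come from resampling loci with replacement; a pair
#' is flagged significant when its CI excludes zero.
#'
#' @inheritParams wc_theta
#' @param n_boot bootstrap replicates over loci (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed optional integer seed for the bootstrap.
#' @return tibble `group1`, `group2`, `theta`, `ci_lower`, `ci_upper`,
#'   `n_boot`, `significant`.
#' @export
pairwise_wc_fst <- function(x, popmap, n_boot = 1000, conf = 0.95,
                            seed = NULL) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  g <- as_geno_matrix(x)
  if (ncol(g) < 2) stop("pairwise F_ST needs at least two loci")
  groups <- unique(popmap$group[!is.na(popmap$group)])
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  with_seed(seed, {
    dplyr::bind_rows(lapply(pairs, function(pr) {
      comp <- wc_theta(x, popmap[popmap$group %in% pr, ])
      av <- comp$a
      dv <- comp$a + comp$b + comp$c
      keep <- !is.na(dv)
      av <- av[keep]; dv <- dv[keep]
      theta <- sum(av) / sum(dv)
      boots <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(av), replace = TRUE)
        sum(av[idx]) / sum(dv[idx])
      }, numeric(1))
      ci <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            na.rm = TRUE, names = FALSE)
      tibble::tibble(group1 = pr[1], group2 = pr[2], theta = theta,
                     ci_lower = ci[1], ci_upper = ci[2],
                     n_boot = n_boot,
                     significant = ci[1] > 0 | ci[2] < 0)
    }))
  })
}

#' Group allele frequencies
#'
#' Alternate-allele frequency of every group at every locus, from
#' pairwise-complete calls.
#'
#' @inheritParams wc_theta
#' @return tibble `group`, `locus_id`, `p` (alternate allele frequency),
#'   `n` (genotyped samples).
#' @export
group_frequencies <- function(x, popmap) {
  g <- as_geno_matrix(x)
  popmap <- popmap[!is.na(popmap$group) & popmap$sample %in% rownames(g), ]
  dplyr::bind_rows(lapply(unique(popmap$group), function(grp) {
    gk <- g[rownames(g) %in% popmap$sample[popmap$group == grp], ,
            drop = FALSE]
    n <- colSums(!is.na(gk))
    tibble::tibble(group = grp, locus_id = colnames(g),
                   p = ifelse(n > 0, colSums(gk, na.rm = TRUE) / (2 * n), NA),
                   n = n)
  }))
}

#' Nei's D_A genetic distance between groups
#'
#' \deqn{D_A = 1 - \frac{1}{L} \sum_l \sum_{\mathrm{alleles}}
#'   \sqrt{x_{la} y_{la}}}
#' over the loci shared (non-missing frequency) by both groups of a pair.
#'
#' @param freqs group allele-frequency tibble from [group_frequencies()]
#'   (columns `group`, `locus_id`, `p`).
#' @return symmetric distance matrix with zero diagonal.
#' @export
nei_da_distance <- function(freqs) {
  pw <- freq_pair_matrix(freqs)
  group_pair_apply(pw, function(px, py) {
    1 - mean(sqrt(px * py) + sqrt((1 - px) * (1 - py)))
  })
}

#' Nei's genetic identity I between groups
#'
#' \deqn{I = \frac{\sum_l \sum_a x_{la} y_{la}}
#'   {\sqrt{(\sum_l \sum_a x_{la}^2)(\sum_l \sum_a y_{la}^2)}}}
#' with `I = 1` for identical frequency profiles and 0 for groups fixed for
#' opposite alleles everywhere.
#'
#' @inheritParams nei_da_distance
#' @return symmetric identity matrix with unit diagonal.
#' @export
nei_identity <- function(freqs) {
  pw <- freq_pair_matrix(freqs)
  out <- group_pair_apply(pw, function(px, py) {
    num <- sum(px * py + (1 - px) * (1 - py))
    den <- sqrt(sum(px^2 + (1 - px)^2) * sum(py^2 + (1 - py)^2))
    if (den == 0) {
      warning("degenerate (zero-variance) frequency profile")
      return(NA_real_)
    }
    num / den
  })
  diag(out) <- 1
  out
}

freq_pair_matrix <- function(freqs) {
  stopifnot(all(c("group", "locus_id", "p") %in% names(freqs)))
  wide <- tidyr::pivot_wider(freqs[c("group", "locus_id", "p")],
                             names_from = "locus_id", values_from = "p")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$group
  m
}

group_pair_apply <- function(pw, f) {
  groups <- rownames(pw)
  out <- matrix(0, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_len(i - 1L)) {
      shared <- !is.na(pw[i, ]) & !is.na(pw[j, ])
      if (!any(shared)) stop("groups ", groups[i], " and ", groups[j],
                             " share no loci")
      v <- f(pw[i, shared], pw[j, shared])
      out[i, j] <- out[j, i] <- v
    }
  }
  out
}
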