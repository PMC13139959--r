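#' PCA of genotype codes
#'
#' Missing calls are imputed with the per-locus mean, columns are centered
#' and left unscaled (so strongly differentiated loci dominate, which is
#' what panel scoring wants), and the decomposition is computed with
#' `prcomp`.
#'
#' @param x genotype table, `snp_geno`, or integer matrix.
#' @param n_axes axes to return (default all informative axes).
#' @return object of class `"genetic_ordination"`: list with `points`
#'   (tibble `sample_id`, `axis1`, `axis2`, ...), `variance` (tibble
#'   `axis`, `pct`) and `method`.
#' @export
pca_genotypes <- function(x, n_axes = NULL) {
  g <- if (is.matrix(x)) x else as_geno_matrix(x)
  mode(g) <- "double"
  mu <- colMeans(g, na.rm = TRUE)
  for (j in which(colSums(is.na(g)) > 0)) {
    g[is.na(g[, j]), j] <- mu[j]
  }
  g[, is.nan(mu)] <- 0
  fit <- prcomp(g, center = TRUE, scale. = FALSE)
  pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  k <- min(n_axes %||% ncol(fit$x), ncol(fit$x))
  pts <- tibble::as_tibble(fit$x[, seq_len(k), drop = FALSE],
                           .name_repair = "minimal")
  names(pts) <- paste0("axis", seq_len(k))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = rownames(g)), pts),
    variance = tibble::tibble(axis = seq_along(pct), pct = pct),
    method = "pca"
  ), class = "genetic_ordination")
}

#' Principal coordinates analysis (classical MDS) of a distance matrix
#'
#' Double-centers the squared distances and eigendecomposes (via
#' `cmdscale`). Axes with negative eigenvalues are dropped with a note;
#' variance percentages are relative to the positive eigenvalues. On
#' Euclidean distances PCoA reproduces PCA coordinates up to sign.
#'
#' @param d symmetric distance matrix with sample dimnames.
#' @param n_axes axes to return (default all positive-eigenvalue axes).
#' @return a `"genetic_ordination"` object (see [pca_genotypes()]).
#' @export
pcoa <- function(d, n_axes = NULL) {
  if (anyNA(d)) stop("distance matrix contains missing entries")
  n <- nrow(d)
  ## cmdscale warns when fewer than k eigenvalues are positive; that is the
  ## expected situation for non-Euclidean genetic distances
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (length(pos) < n - 1) {
    message(sprintf("dropped %d non-positive-eigenvalue axes",
                    n - 1 - length(pos)))
  }
  k <- min(n_axes %||% length(pos), length(pos))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  out <- tibble::as_tibble(pts, .name_repair = "minimal")
  names(out) <- paste0("axis", seq_len(k))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = rownames(d)), out),
    variance = tibble::tibble(axis = seq_along(pos),
                              pct = 100 * eig[pos] / sum(eig[pos])),
    method = "pcoa"
  ), class = "genetic_ordination")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genetic_ordination <- function(x, ...) {
  cat(sprintf("<genetic_ordination> %s, %d samples\n", x$method,
              nrow(x$points)))
  v <- x$variance$pct
  cat(sprintf("  axis 1: %.2f%%, axis 2: %.2f%% of variance\n",
              v[1], if (length(v) > 1) v[2] else NA))
  invisible(x)
}

#' Plot an ordination coloured by group
#'
#' @param ord a `"genetic_ordination"` object.
#' @param popmap optional [pop_map()] for colouring points by group.
#' @param axes which two axes to draw (default 1:2).
#' @return a ggplot object.
#' @export
plot_ordination <- function(ord, popmap = NULL, axes = c(1, 2)) {
  pts <- ord$points
  ax <- paste0("axis", axes)
  df <- pts[c("sample_id", ax)]
  names(df) <- c("sample_id", "x", "y")
  df$group <- if (is.null(popmap)) "sample" else
    popmap$group[match(df$sample_id, popmap$sample)]
  lab <- sprintf("%s %d (%.1f%%)", toupper(ord$method), axes,
                 ord$variance$pct[axes])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = lab[1], y = lab[2], colour = "group") +
    ggplot2::theme_minimal()
}
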