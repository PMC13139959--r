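#' UPGMA dendrogram with optional locus-resampled bootstrap support
#'
#' Average-linkage agglomerative clustering with ultrametric node heights
#' (the height of a merge is half the average-linkage distance of the pair
#' it joins). Tied merge candidates are resolved deterministically by
#' joining the pair whose smallest original sample indices come first.
#'
#' Bootstrap support is computed by resampling loci with replacement from
#' `geno`, recomputing the distance matrix with `dist_fun` and the tree,
#' and counting the fraction of replicate trees containing each original
#' bipartition (attached as `node.label`, in percent).
#'
#' @param d symmetric distance matrix with sample dimnames, no missing
#'   entries.
#' @param geno genotype table used for bootstrap locus resampling
#'   (required when `n_boot > 0`).
#' @param n_boot number of bootstrap replicates (default 0, no support).
#' @param dist_fun distance function applied to a genotype table (default
#'   [allele_sharing_distance()]).
#' @param seed optional integer seed for the bootstrap.
#' @return object of class `"upgma_tree"`: list with `tree` (an `ape`
#'   `"phylo"`, ultrametric, `node.label` = support when bootstrapped),
#'   `merges` (tibble: step, height, members joined) and `n_boot`.
#' @export
upgma_tree <- function(d, geno = NULL, n_boot = 0,
                       dist_fun = allele_sharing_distance, seed = NULL) {
  if (anyNA(d)) stop("distance matrix contains missing entries")
  stopifnot(isSymmetric(unname(d)), !is.null(rownames(d)))
  fit <- upgma_merge(d)
  tree <- ape::read.tree(text = upgma_newick(fit, rownames(d)))
  support <- NULL
  if (n_boot > 0) {
    if (is.null(geno)) stop("bootstrap needs the genotype table")
    g <- as_geno_matrix(geno)
    stopifnot(setequal(rownames(g), rownames(d)))
    boot_trees <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
      idx <- sample.int(ncol(g), replace = TRUE)
      gb <- g[, idx, drop = FALSE]
      colnames(gb) <- paste0("L", seq_len(ncol(gb)))
      db <- dist_fun(as_geno_tbl(gb))
      ape::read.tree(text = upgma_newick(upgma_merge(db), rownames(db)))
    }))
    counts <- ape::prop.clades(tree, boot_trees, rooted = TRUE)
    counts[is.na(counts)] <- 0
    support <- round(100 * counts / n_boot, 1)
    tree$node.label <- support
  }
  structure(list(tree = tree, merges = fit$merges, n_boot = n_boot,
                 support = support),
            class = "upgma_tree")
}

## agglomeration engine; returns hclust-style merge codes plus node heights
upgma_merge <- function(d) {
  n <- nrow(d)
  if (n < 2) stop("need at least two samples")
  D <- as.matrix(d)
  code <- -seq_len(n)                 # hclust convention
  size <- rep(1L, n)
  minmem <- seq_len(n)                # smallest original index per cluster
  alive <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- character(n - 1L)
  labels <- rownames(d)
  groups <- lapply(seq_len(n), function(i) labels[i])
  for (step in seq_len(n - 1L)) {
    idx <- which(alive)
    sub <- D[idx, idx, drop = FALSE]
    ut <- upper.tri(sub)
    dmin <- min(sub[ut])
    cand <- which(ut & sub <= dmin + 1e-12, arr.ind = TRUE)
    ## tie-break: smallest original member indices first
    key1 <- pmin(minmem[idx[cand[, 1]]], minmem[idx[cand[, 2]]])
    key2 <- pmax(minmem[idx[cand[, 1]]], minmem[idx[cand[, 2]]])
    pick <- order(key1, key2)[1]
    i <- idx[cand[pick, 1]]
    j <- idx[cand[pick, 2]]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- D[i, j] / 2
    ## average-linkage update into slot i
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      D[i, others] <- D[others, i] <-
        (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    minmem[i] <- min(minmem[i], minmem[j])
    groups[[i]] <- c(groups[[i]], groups[[j]])
    members[step] <- paste(sort(groups[[i]]), collapse = ",")
    code[i] <- step
    alive[j] <- FALSE
  }
  list(merge = merge, height = height,
       merges = tibble::tibble(step = seq_len(n - 1L), height = height,
                               members = members))
}

upgma_newick <- function(fit, labels) {
  node_str <- function(code, parent_h) {
    if (code < 0) {
      sprintf("%s:%.15g", labels[-code], parent_h)
    } else {
      h <- fit$height[code]
      kids <- fit$merge[code, ]
      inner <- paste(node_str(kids[1], h), node_str(kids[2], h), sep = ",")
      if (is.na(parent_h)) sprintf("(%s);", inner)
      else sprintf("(%s):%.15g", inner, parent_h - h)
    }
  }
  node_str(nrow(fit$merge), NA_real_)
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree> %d tips", length(x$tree$tip.label)))
  if (x$n_boot > 0) cat(sprintf(", %d bootstrap replicates", x$n_boot))
  cat("\n")
  print(x$tree)
  invisible(x)
}
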